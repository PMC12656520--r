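"","oleic","linoleic","palmitic","stearic","linolenic","arachidic","behenic","eicosenoic","Tb","psi_b50","theta_HT"
"cv1",42.55,41.48,8.54,5.69,0.472,0.731,0.124,0.178,12.36,-0.599,687.4
"cv2",41.12,44.15,8.99,4.57,0.309,0.42,0.149,0.285,13.26,-0.547,798
"cv3",40.37,42.52,7.85,5.97,0.412,0.718,0.147,0.22,13.14,-0.632,931.7
"cv4",39.98,46.27,8.21,4.79,0.401,0.665,0.08,0.251,13.34,-0.421,990.5
"cv5",38.69,42.58,9.13,4.36,0.448,0.643,0.077,0.184,14.4,-0.575,1336.2
"cv6",43.1,41.24,10.01,5.42,0.4,0.707,0.148,0.24,12.26,-0.644,504
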