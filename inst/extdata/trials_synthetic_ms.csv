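"participant","condition","standard_ms","comparison_ms","response","rep"
"P01","baseline",600,200,0,1
"P01","baseline",600,200,0,2
"P01","baseline",600,400,0,1
"P01","baseline",600,400,0,2
"P01","baseline",600,500,0,1
"P01","baseline",600,500,0,2
"P01","baseline",600,600,1,1
"P01","baseline",600,600,0,2
"P01","baseline",600,700,0,1
"P01","baseline",600,700,0,2
"P01","baseline",600,800,1,1
"P01","baseline",600,800,1,2
"P01","baseline",600,1000,1,1
"P01","baseline",600,1000,1,2
"P01","adaptation",600,200,0,1
"P01","adaptation",600,200,0,2
"P01","adaptation",600,400,1,1
"P01","adaptation",600,400,1,2
"P01","adaptation",600,500,0,1
"P01","adaptation",600,500,1,2
"P01","adaptation",600,600,1,1
"P01","adaptation",600,600,0,2
"P01","adaptation",600,700,1,1
"P01","adaptation",600,700,1,2
"P01","adaptation",600,800,1,1
"P01","adaptation",600,800,1,2
"P01","adaptation",600,1000,1,1
"P01","adaptation",600,1000,1,2
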