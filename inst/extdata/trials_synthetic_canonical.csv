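"participant","condition","standard_ms","comparison_pct","response","rep"
"P01","baseline",600,-66.67,0,1
"P01","baseline",600,-66.67,0,2
"P01","baseline",600,-33.33,0,1
"P01","baseline",600,-33.33,0,2
"P01","baseline",600,-16.67,0,1
"P01","baseline",600,-16.67,0,2
"P01","baseline",600,0,1,1
"P01","baseline",600,0,0,2
"P01","baseline",600,16.67,0,1
"P01","baseline",600,16.67,0,2
"P01","baseline",600,33.33,1,1
"P01","baseline",600,33.33,1,2
"P01","baseline",600,66.67,1,1
"P01","baseline",600,66.67,1,2
"P02","baseline",600,-66.67,0,1
"P02","baseline",600,-66.67,0,2
"P02","baseline",600,-33.33,1,1
"P02","baseline",600,-33.33,0,2
"P02","baseline",600,-16.67,0,1
"P02","baseline",600,-16.67,0,2
"P02","baseline",600,0,1,1
"P02","baseline",600,0,0,2
"P02","baseline",600,16.67,0,1
"P02","baseline",600,16.67,0,2
"P02","baseline",600,33.33,1,1
"P02","baseline",600,33.33,1,2
"P02","baseline",600,66.67,1,1
"P02","baseline",600,66.67,1,2
"P01","adaptation",600,-66.67,0,1
"P01","adaptation",600,-66.67,0,2
"P01","adaptation",600,-33.33,1,1
"P01","adaptation",600,-33.33,1,2
"P01","adaptation",600,-16.67,0,1
"P01","adaptation",600,-16.67,1,2
"P01","adaptation",600,0,1,1
"P01","adaptation",600,0,0,2
"P01","adaptation",600,16.67,1,1
"P01","adaptation",600,16.67,1,2
"P01","adaptation",600,33.33,1,1
"P01","adaptation",600,33.33,1,2
"P01","adaptation",600,66.67,1,1
"P01","adaptation",600,66.67,1,2
"P02","adaptation",600,-66.67,0,1
"P02","adaptation",600,-66.67,1,2
"P02","adaptation",600,-33.33,0,1
"P02","adaptation",600,-33.33,1,2
"P02","adaptation",600,-16.67,1,1
"P02","adaptation",600,-16.67,1,2
"P02","adaptation",600,0,0,1
"P02","adaptation",600,0,1,2
"P02","adaptation",600,16.67,1,1
"P02","adaptation",600,16.67,1,2
"P02","adaptation",600,33.33,1,1
"P02","adaptation",600,33.33,1,2
"P02","adaptation",600,66.67,1,1
"P02","adaptation",600,66.67,1,2
"P01","baseline",1200,-66.67,0,1
"P01","baseline",1200,-66.67,0,2
"P01","baseline",1200,-33.33,0,1
"P01","baseline",1200,-33.33,0,2
"P01","baseline",1200,-16.67,0,1
"P01","baseline",1200,-16.67,1,2
"P01","baseline",1200,0,1,1
"P01","baseline",1200,0,1,2
"P01","baseline",1200,16.67,0,1
"P01","baseline",1200,16.67,1,2
"P01","baseline",1200,33.33,1,1
"P01","baseline",1200,33.33,0,2
"P01","baseline",1200,66.67,1,1
"P01","baseline",1200,66.67,1,2
"P02","baseline",1200,-66.67,0,1
"P02","baseline",1200,-66.67,0,2
"P02","baseline",1200,-33.33,0,1
"P02","baseline",1200,-33.33,0,2
"P02","baseline",1200,-16.67,0,1
"P02","baseline",1200,-16.67,1,2
"P02","baseline",1200,0,1,1
"P02","baseline",1200,0,1,2
"P02","baseline",1200,16.67,1,1
"P02","baseline",1200,16.67,1,2
"P02","baseline",1200,33.33,1,1
"P02","baseline",1200,33.33,1,2
"P02","baseline",1200,66.67,1,1
"P02","baseline",1200,66.67,1,2
"P01","adaptation",1200,-66.67,0,1
"P01","adaptation",1200,-66.67,0,2
"P01","adaptation",1200,-33.33,0,1
"P01","adaptation",1200,-33.33,0,2
"P01","adaptation",1200,-16.67,0,1
"P01","adaptation",1200,-16.67,0,2
"P01","adaptation",1200,0,0,1
"P01","adaptation",1200,0,1,2
"P01","adaptation",1200,16.67,1,1
"P01","adaptation",1200,16.67,0,2
"P01","adaptation",1200,33.33,0,1
"P01","adaptation",1200,33.33,1,2
"P01","adaptation",1200,66.67,1,1
"P01","adaptation",1200,66.67,1,2
"P02","adaptation",1200,-66.67,0,1
"P02","adaptation",1200,-66.67,0,2
"P02","adaptation",1200,-33.33,0,1
"P02","adaptation",1200,-33.33,0,2
"P02","adaptation",1200,-16.67,0,1
"P02","adaptation",1200,-16.67,0,2
"P02","adaptation",1200,0,0,1
"P02","adaptation",1200,0,0,2
"P02","adaptation",1200,16.67,0,1
"P02","adaptation",1200,16.67,1,2
"P02","adaptation",1200,33.33,1,1
"P02","adaptation",1200,33.33,1,2
"P02","adaptation",1200,66.67,1,1
"P02","adaptation",1200,66.67,1,2
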