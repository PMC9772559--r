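"gene","cycle"
"cbbL","C"
"aclB","C"
"pmoA","C"
"mmoX","C"
"mcrA","C"
"amyA","C"
"amyX","C"
"apu","C"
"abfA","C"
"cdh","C"
"cex","C"
"chiA","C"
"exg","C"
"glx","C"
"lig","C"
"mnp","C"
"naglu","C"
"pgu","C"
"sga","C"
"xylA","C"
"bglX","C"
"pel","C"
"amoA_AOA","N"
"amoA_AOB","N"
"hao","N"
"nxrA","N"
"narG","N"
"napA","N"
"nirK","N"
"nirS","N"
"norB","N"
"nosZ","N"
"nifH","N"
"hzsB","N"
"nrfA","N"
"ureC","N"
"gdh","N"
"glnA","N"
"nasA","N"
"nirB","N"
"nrfH","N"
"nifD","N"
"nifK","N"
"anfG","N"
"napB","N"
"norC","N"
"hzo","N"
"phoD","P"
"phoC","P"
"phoX","P"
"ppx","P"
"ppk","P"
"pqqC","P"
"gcd","P"
"phnK","P"
"phnX","P"
"pstS","P"
"phoN","P"
"bpp","P"
"dsrA","S"
"dsrB","S"
"aprA","S"
"soxB","S"
"soxY","S"
"sqr","S"
"fccA","S"
"cysJ","S"
"sir","S"
"sreA","S"
"soxA","S"
"tst","S"
"sat","S"
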