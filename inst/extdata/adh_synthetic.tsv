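# positions: 1.5120053346401283 20.5200948281330113 32.5376678001862416 37.1358150319585150 52.9903492890298367 59.5681983988515782 76.4842852451202475 81.3806770811370939 86.8527688283296726 93.4307179014643054 99.3478240622541762 101.9310227605376582 103.8810631869739609 114.3489103100566808 117.6999391533114476 119.4108311409496821 125.7137087349452997 132.6378978788852692 134.0931658117216614 140.2708626354252601 175.8160277377600380 185.9191226783103730 188.3927332379220161 192.7873577565403025 199.4708815380039368 208.9946642895473587 240.6331414810755405 242.1689877232859658 257.9518525881006212 311.2349906936287880 318.3702032413279426 322.8693555271979108 324.7286440091128839 333.7208670194736442 337.8725526854395866 338.9170866907817867 347.7414113188232818 360.3332859613519759 361.5075180905895991 364.8622671405977371 385.8193221716076096 386.0176067797038968 399.8478258430845358
# seq_length: 400
0110000111111001001000110010000011000110000
0000101000111001101011000000001000011001000
1000000000000010000111000100001000011000110
1000000000000010000111000000100010000100001
0000101000111001101011001000001000011001000
1000000000111001001000100000000111000100000
1001000000000010010100110010000011000110000
0000110000111101001000100001100010000100001
0000110000111101001000100000000010000100000
1001000000000010000100110010000011000110000
1000000000111001001000100010010011100110000
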