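name,description,true_abv,labeled_abv,voc_multiplier
C4,Pure Malt Beer,4.0,4.0,1.00
C4M,Malzbier Beer,4.0,4.0,1.15
C4.5,Pilsen Beer,4.5,4.5,1.00
C4.6,Pure Malt Beer I,4.6,4.6,1.00
C5,Pure Malt Beer II,5.0,5.0,1.00
C5.4,Black Beer Stout,5.4,5.4,1.00
C7.9,Mixed Beer,7.9,7.9,1.00
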