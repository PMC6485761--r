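>hairpin_example
-12.4	..........((((((....))))))..............
-10.1	..........((((......))))................
-9.7	........................................
>open_chain
-3.2	....................
-1.0	..((............))..
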