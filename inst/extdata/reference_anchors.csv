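ga_weeks,time_day,arm,concentration_mg_dl
24,0,no_ibuprofen,0.383
24,3,no_ibuprofen,0.876
24,14,no_ibuprofen,0.500
24,17,no_ibuprofen,0.462
24,28,no_ibuprofen,0.375
24,31,no_ibuprofen,0.365
27,0,no_ibuprofen,0.462
27,3,no_ibuprofen,0.830
27,14,no_ibuprofen,0.439
27,17,no_ibuprofen,0.411
27,28,no_ibuprofen,0.345
27,31,no_ibuprofen,0.339
29,0,no_ibuprofen,0.518
29,3,no_ibuprofen,0.807
29,14,no_ibuprofen,0.408
29,17,no_ibuprofen,0.384
29,28,no_ibuprofen,0.334
29,31,no_ibuprofen,0.328
32,0,no_ibuprofen,0.607
32,3,no_ibuprofen,0.772
32,14,no_ibuprofen,0.374
32,17,no_ibuprofen,0.355
32,28,no_ibuprofen,0.321
32,31,no_ibuprofen,0.318
24,0,ibuprofen,0.383
24,3,ibuprofen,0.906
24,14,ibuprofen,0.500
24,17,ibuprofen,0.472
24,28,ibuprofen,0.375
24,31,ibuprofen,0.371
27,0,ibuprofen,0.462
27,3,ibuprofen,0.857
27,14,ibuprofen,0.439
27,17,ibuprofen,0.419
27,28,ibuprofen,0.345
27,31,ibuprofen,0.344
29,0,ibuprofen,0.518
29,3,ibuprofen,0.832
29,14,ibuprofen,0.408
29,17,ibuprofen,0.391
29,28,ibuprofen,0.334
29,31,ibuprofen,0.333
32,0,ibuprofen,0.607
32,3,ibuprofen,0.795
32,14,ibuprofen,0.374
32,17,ibuprofen,0.360
32,28,ibuprofen,0.321
32,31,ibuprofen,0.322
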