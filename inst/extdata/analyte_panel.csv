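analyte_id,formula,n_exchangeable,precursor_mz,product_mz,pool_mean_ug_g,pool_cv
T-CA,C26H44NO7S,14,514.2,80,80,0.25
T-aMCA,C26H44NO7S,14,514.2,80,6,0.25
T-bMCA,C26H44NO7S,10,514.2,80,25,0.25
T-CDCA,C26H44NO6S,18,498.2,80,7,0.25
T-DCA,C26H44NO6S,10,498.2,80,5,0.25
palmitate,C16H31O2,22,255.2,NA,2500,0.25
cholesterol,C18H31,20,247.2,NA,2000,0.25
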