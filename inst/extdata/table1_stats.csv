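time_step,n_cells,n_mitosis,n_appearance,mse
1,3,0,3,0
2,5,2,0,4
3,7,0,2,1
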