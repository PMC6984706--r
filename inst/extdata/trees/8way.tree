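(((H1|1000,H2|1000)I11|875,(H3|1000,H4|1000)I12|875)I1|750,((H5|1000,H6|1000)I21|875,(H7|1000,H8|1000)I22|875)I2|750)Root|500;
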