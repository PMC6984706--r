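(A|3000,B|4000)Root|2000;
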