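((A|1250,B|1500)AB|1125,(C|1750,(D|2000,E|2000)DE|1688)CDE|1375)Root|1000;
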