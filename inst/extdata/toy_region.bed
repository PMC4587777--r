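# toy region (0-based half-open); 1-based chr21:43,809,418-44,828,031
chr21	43809417	44828031
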