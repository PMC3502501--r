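library	total_tags	unique_tags
C57-Os/+	26599	11014
ROP-Os/+	22989	9580
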