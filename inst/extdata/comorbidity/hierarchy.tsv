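method	dominant	suppressed
charlson_deyo	dm_comp	dm
charlson_deyo	severe_liver	mild_liver
charlson_deyo	mets	cancer
charlson_romano	dm_comp	dm
charlson_romano	severe_liver	mild_liver
charlson_romano	mets	cancer
elixhauser	dm_comp	dm_uncomp
elixhauser	mets	solid_tumor
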