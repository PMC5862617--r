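sample_id,diagnosis,location,sex,age
PA01,PA,Cerebellum (I),M,17
PA02,PA,Cerebellum (I),F,7
PA03,PA,Cerebellum (I),M,12
PA04,PA,Frontal lobe (S),F,2
PA05,PA,Frontal lobe (S),M,1
PA06,PA,Optic chiasm (S),M,1
PA07,PA,Cerebellum (I),F,13
PA08,PA,Cerebral hemisphere (S),F,7
PA09,PA,Cerebellum (I),M,11
PA10,PA,Optic chiasm (S),M,2
PA11,PA,Cerebellum (I),F,9
PA12,PA,Temporal lobe (S),F,10
PA13,PA,Cerebellum (I),F,3
PA14,PA,Cerebellum (I),M,11
PA15,PA,Hypothalamus (S),M,5
PA16,PA,Cerebellum (I),M,3
PA17,PA,Cerebellum (I),M,5
PA18,PA,Hypothalamus (S),M,3
PA19,PA,Frontal lobe (S),F,3
PA20,PA,Hypothalamus (S),F,1
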