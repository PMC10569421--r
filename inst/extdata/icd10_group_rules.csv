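kind,code,start,end,group
exact,F01.1,,,cerebrovascular
exact,G93.1,,,cerebrovascular
exact,H43.1,,,bleeding
exact,H11.3,,,bleeding
exact,D68.3,,,bleeding
exact,M25.0,,,bleeding
exact,S06.6,,,bleeding
exact,S27.2,,,bleeding
exact,T81.0,,,bleeding
exact,I33.0,,,infection
exact,I38,,,infection
exact,K85.9,,,infection
exact,K80.4,,,infection
exact,K35.8,,,infection
exact,M46.3,,,infection
exact,M86.9,,,infection
exact,N13.6,,,infection
exact,B02.3,,,other
exact,I85.9,,,gastrointestinal
exact,K86.1,,,endocrine_metabolic
exact,E87.7,,,cardiac
exact,Q21.1,,,cardiac
exact,T46.0,,,cardiac
exact,T82.0,,,cardiac
exact,T82.8,,,peripheral_vascular
exact,K55.9,,,peripheral_vascular
exact,I31.9,,,peripheral_vascular
exact,T79.6,,,osteoarticular
exact,R22.4,,,osteoarticular
exact,R29.6,,,frailty
range,,A00,B99,infection
range,,C00,D48,cancer
range,,D50,D89,haematological
range,,E00,E90,endocrine_metabolic
range,,I05,I09,cardiac
range,,I10,I15,peripheral_vascular
range,,I20,I25,cardiac
range,,I26,I28,peripheral_vascular
range,,I30,I52,cardiac
range,,I60,I62,bleeding
range,,I63,I69,cerebrovascular
range,,I70,I99,peripheral_vascular
range,,J00,J22,infection
range,,J23,J99,respiratory
range,,K00,K93,gastrointestinal
range,,L00,L08,infection
range,,L89,L89,frailty
range,,M00,M99,osteoarticular
range,,N00,N29,renal
range,,R00,R00,cardiac
range,,R53,R53,frailty
range,,S00,T14,osteoarticular
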