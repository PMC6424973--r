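name,formula,positions
phloroglucinol,C6H6O3,"1:OH,3:OH,5:OH"
resorcinol,C6H6O2,"1:OH,3:OH"
2-chlororesorcinol,C6H5ClO2,"1:OH,2:Cl,3:OH"
orcinol,C7H8O2,"1:OH,3:OH,5:CH3"
3-5-dihydroxybenzyl-alcohol,C7H8O3,"1:CH2OH,3:OH,5:OH"
2-4-6-trihydroxyacetophenone,C8H8O4,"1:COCH3,2:OH,4:OH,6:OH"
3-aminophenol,C6H7NO,"1:OH,3:NH2"
m-phenylenediamine,C6H8N2,"1:NH2,3:NH2"
3-nitrophenol,C6H5NO3,"1:OH,3:NO2"
resveratrol,C14H12O3,"1:styrenyl,3:OH,5:OH"
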