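pdb_id,name,expression_system,v_m,resolution
2BO4,Mannosylglycerate synthase,E. coli,5.50,1.95
3DER,Dipeptide epimerase,E. coli,4.77,1.90
2W5F,Endo-1-4-beta-D-xylanase,E. coli,4.74,1.90
2W5E,Astrovirus serine protease,E. coli,4.71,2.00
1KOR,Argininosuccinate synthetase,E. coli,4.53,1.95
1TG7,Beta-galactosidase,Penicillium sp.,4.50,1.90
3IA2,Arylesterase,E. coli,4.46,1.65
2ZXQ,Endo-alpha-N-acetylgalactosaminidase,E. coli,4.38,2.00
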