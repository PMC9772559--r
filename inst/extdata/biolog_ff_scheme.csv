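"well","substrate","group","replicate"
"A1","Water","control",1
"A2","N-Acetyl-D-glucosamine","carbohydrates",1
"A3","N-Acetyl-D-mannosamine","carbohydrates",1
"A4","D-Arabinose","carbohydrates",1
"A5","L-Arabinose","carbohydrates",1
"A6","D-Cellobiose","carbohydrates",1
"A7","D-Fructose","carbohydrates",1
"A8","L-Fucose","carbohydrates",1
"A9","D-Galactose","carbohydrates",1
"A10","D-Glucosamine","carbohydrates",1
"A11","alpha-D-Glucose","carbohydrates",1
"A12","alpha-D-Lactose","carbohydrates",1
"B1","Lactulose","carbohydrates",1
"B2","Maltose","carbohydrates",1
"B3","Maltotriose","carbohydrates",1
"B4","D-Mannose","carbohydrates",1
"B5","D-Melezitose","carbohydrates",1
"B6","D-Melibiose","carbohydrates",1
"B7","Palatinose","carbohydrates",1
"B8","D-Psicose","carbohydrates",1
"B9","D-Raffinose","carbohydrates",1
"B10","L-Rhamnose","carbohydrates",1
"B11","D-Ribose","carbohydrates",1
"B12","L-Sorbose","carbohydrates",1
"C1","Stachyose","carbohydrates",1
"C2","Sucrose","carbohydrates",1
"C3","D-Tagatose","carbohydrates",1
"C4","D-Trehalose","carbohydrates",1
"C5","Turanose","carbohydrates",1
"C6","D-Xylose","carbohydrates",1
"C7","Acetic acid","carboxylic acids",1
"C8","gamma-Aminobutyric acid","carboxylic acids",1
"C9","Bromosuccinic acid","carboxylic acids",1
"C10","Fumaric acid","carboxylic acids",1
"C11","beta-Hydroxybutyric acid","carboxylic acids",1
"C12","gamma-Hydroxybutyric acid","carboxylic acids",1
"D1","p-Hydroxyphenylacetic acid","carboxylic acids",1
"D2","alpha-Ketoglutaric acid","carboxylic acids",1
"D3","L-Lactic acid","carboxylic acids",1
"D4","D-Malic acid","carboxylic acids",1
"D5","L-Malic acid","carboxylic acids",1
"D6","Quinic acid","carboxylic acids",1
"D7","D-Saccharic acid","carboxylic acids",1
"D8","Sebacic acid","carboxylic acids",1
"D9","Succinic acid","carboxylic acids",1
"D10","D-Galacturonic acid","carboxylic acids",1
"D11","D-Gluconic acid","carboxylic acids",1
"D12","D-Glucuronic acid","carboxylic acids",1
"E1","2-Keto-D-gluconic acid","carboxylic acids",1
"E2","Citric acid","carboxylic acids",1
"E3","L-Alanine","amino acids",1
"E4","L-Alanyl-glycine","amino acids",1
"E5","L-Asparagine","amino acids",1
"E6","L-Aspartic acid","amino acids",1
"E7","L-Glutamic acid","amino acids",1
"E8","Glycyl-L-glutamic acid","amino acids",1
"E9","L-Ornithine","amino acids",1
"E10","L-Phenylalanine","amino acids",1
"E11","L-Proline","amino acids",1
"E12","L-Serine","amino acids",1
"F1","Amygdalin","glycosides",1
"F2","Arbutin","glycosides",1
"F3","Salicin","glycosides",1
"F4","alpha-Methyl-D-glucoside","glycosides",1
"F5","alpha-Cyclodextrin","polymers",1
"F6","beta-Cyclodextrin","polymers",1
"F7","Dextrin","polymers",1
"F8","Glycogen","polymers",1
"F9","Tween 80","polymers",1
"F10","Adonitol","polyols",1
"F11","D-Arabitol","polyols",1
"F12","L-Arabitol","polyols",1
"G1","i-Erythritol","polyols",1
"G2","Glycerol","polyols",1
"G3","m-Inositol","polyols",1
"G4","Maltitol","polyols",1
"G5","D-Mannitol","polyols",1
"G6","D-Sorbitol","polyols",1
"G7","Xylitol","polyols",1
"G8","Alaninamide","amines and amides",1
"G9","2-Aminoethanol","amines and amides",1
"G10","Glucuronamide","amines and amides",1
"G11","Putrescine","amines and amides",1
"G12","Succinamic acid","amines and amides",1
"H1","N-Acetyl-L-glutamic acid","amines and amides",1
"H2","L-Pyroglutamic acid","amines and amides",1
"H3","Phenylethylamine","amines and amides",1
"H4","Glycyl-L-aspartic acid","amines and amides",1
"H5","Adenosine","miscellaneous",1
"H6","Uridine","miscellaneous",1
"H7","Adenosine-5-monophosphate","miscellaneous",1
"H8","Glucose-1-phosphate","miscellaneous",1
"H9","D-Lactic acid methyl ester","miscellaneous",1
"H10","Succinic acid mono-methyl ester","miscellaneous",1
"H11","Pyruvic acid methyl ester","miscellaneous",1
"H12","Sedoheptulosan","miscellaneous",1
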