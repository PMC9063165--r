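feature_id	function_label	effect
K02573	Ferredoxin type protein NapG	-0.2774
K01838	Beta phosphoglucomutase	-0.2398
K02773	PTS system galactitol specific IIA component	-0.2318
K07497	Putative transposase	-0.2010
K01089	Imidazoleglycerol phosphate dehydratase histidinol phosphatase	-0.1793
K07448	Restriction system protein	-0.1769
K06223	DNA adenine methylase	-0.1179
K01051	Pectinesterase	-0.1030
K02041	Phosphonate transport system ATP binding protein	-0.0841
K11065	Thiol peroxidase atypical 2 Cys peroxiredoxin	-0.0733
K07243	High affinity iron transporter	-0.0676
K00244	Fumarate reductase flavoprotein subunit	-0.0548
K01673	Carbonic anhydrase	-0.0487
K00384	Thioredoxin reductase NADPH	0.0208
K01649	2 isopropylmalate synthase	0.0219
K02563	UDP N acetylglucosamine N acetylmuramyl pentapeptide pyrophosphoryl undecaprenol N acetylglucosamine transferase	0.0235
K02120	V A type H Na transporting ATPase subunit D	0.0322
K02909	Large subunit ribosomal protein L31	0.0340
K00031	Isocitrate dehydrogenase	0.0410
K03296	Hydrophobic amphiphilic exporter 1 mainly G bacteria HAE1 family	0.0474
K18369	Alcohol dehydrogenase	0.0634
K08963	Methylthioribose 1 phosphate isomerase	0.0675
K13940	Dihydroneopterin aldolase 2 amino 4 hydroxy 6 hydroxymethyldihydropteridine diphosphokinase	0.1349
K00549	5 methyltetrahydropteroyltriglutamate homocysteine methyltransferase	0.1676
K02083	Allantoate deiminase	0.2029
K10547	Putative multiple sugar transport system permease protein	0.2212
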