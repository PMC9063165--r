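feature_id	function_label	effect
GO:0047980	Hippurate hydrolase activity	-0.1968
GO:0031647	Regulation of protein stability	-0.1494
GO:0030412	Formimidoyltetrahydrofolate cyclodeaminase activity	-0.1463
GO:0008953	Penicillin amidase activity	-0.1402
GO:0008514	Organic anion transmembrane transporter activity	-0.1301
GO:0004793	Threonine aldolase activity	-0.1083
GO:0035556	Intracellular signal transduction	-0.1056
GO:0070008	Serine type exopeptidase activity	-0.0876
GO:0004038	Allantoinase activity	-0.0793
GO:0071973	Bacterial type flagellum dependent cell motility	-0.0539
GO:0008452	RNA ligase activity	0.0249
GO:0004866	Endopeptidase inhibitor activity	0.0562
GO:0004008	Copper exporting ATPase activity	0.0600
GO:0050385	Ureidoglycolate lyase activity	0.0683
GO:0008792	Arginine decarboxylase activity	0.0961
GO:0030596	Alpha-L-rhamnosidase activity	0.1039
GO:0033727	Aldehyde dehydrogenase FAD independent activity	0.1982
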