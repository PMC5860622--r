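transcriptome	total_contigs	contigs_with_homolog	human_homologs	contigs_in_interactome	n_interactions	average_degree	pct_plen1
Adamidi	18547	9478	5187	4903	32626	6.657	36.8
Blythe	24008	10930	5564	5929	32892	5.548	34.7
Consolidated	23545	12775	5809	7098	53609	7.553	30.8
Dresden	40480	14626	5889	7713	68805	8.921	30.4
GBRNA	4675	2314	1547	983	3158	3.213	55.5
Graveley	19503	8475	4329	3796	14254	3.755	30.6
Illuminaplus	28926	10090	5182	5263	29574	5.619	36.8
Newmark	53898	20665	6359	11188	100138	8.950	39.0
Pearson	25889	10465	5656	5176	30538	5.810	31.0
Smed454	46602	14720	4711	8734	112512	4.061	57.4
SmedGD	32615	12904	5947	6715	55939	8.330	28.4
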