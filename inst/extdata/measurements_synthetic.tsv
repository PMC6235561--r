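metabolite	condition	mean_uM	se_uM	n
3PGA	HC	71.3952569753279	7.24344323260003	4
BPGA	HC	76.5160040664303	2.53692011974545	4
DHAP	HC	110.841699313327	6.73702585825512	4
E4P	HC	183.563377406159	6.46997362141878	4
F6P	HC	114.411906162425	14.518926039767	4
FBP	HC	211.412932047376	14.846054600444	4
G6P	HC	47.7870875108746	0.865843673671902	4
GAP	HC	167.263119211032	10.5231126291685	4
MAL	HC	70.0019574092397	7.38382509889591	4
OAA	HC	341.483094241712	41.8305337521346	4
R5P	HC	121.050996640236	4.97920667442851	4
Ru5P	HC	155.22654758349	22.270410772123	4
RuBP	HC	123.578711425332	7.7354553537128	4
S7P	HC	79.6909936754357	4.60742421135558	4
SBP	HC	267.063698134259	20.8293703317058	4
X5P	HC	143.628440068137	12.9687094376808	4
3PGA	LC*	275.645411937424	11.8753571349369	4
BPGA	LC*	62.0969705811736	4.83175298889089	4
DHAP	LC*	60.584995633079	5.06400968703854	4
E4P	LC*	103.212336060117	3.00246637480992	4
F6P	LC*	154.189589629142	4.00395589734237	4
FBP	LC*	66.6667095954507	2.73309340401366	4
G6P	LC*	168.209035386439	15.0884554242412	4
GAP	LC*	303.071104748587	20.3760795664746	4
MAL	LC*	212.811930001373	20.765964135297	4
OAA	LC*	150.681995464647	13.3916827939019	4
R5P	LC*	82.1966780740492	7.4755596947164	4
Ru5P	LC*	146.665778918332	9.23991851903282	4
RuBP	LC*	106.381383118497	9.10293614298668	4
S7P	LC*	156.24995098529	5.6360459685642	4
SBP	LC*	67.9291089004482	5.59510557564833	4
X5P	LC*	110.056993127616	6.87954639709725	4
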