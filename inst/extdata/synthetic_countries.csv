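"country","taxon","lat","lon","hdi_1980","hdi_1990","hdi_2000","hdi_2005","hdi_2010","hdi_2012","catholic","protestant","orthodox","muslim","other","communism"
"Country01","lang01",49.6051,76.1311,NA,0.7694,0.7433,0.7539,0.7623,0.762,25.7,7.3,30.4,14.7,21.9,0
"Country02","lang02",21.9723,5.5369,NA,0.5099,0.5292,0.5512,0.5783,0.5614,35.1,2.6,32.4,27.2,2.7,1
"Country03","lang03",35.456,35.7041,NA,0.4652,0.4772,0.5039,0.5059,0.507,6.4,1.9,23.1,66.2,2.4,0
"Country04","lang04",39.5998,9.0173,0.5537,0.5682,0.5788,0.5877,0.6089,0.5901,22.6,21.2,36.8,17.9,1.5,1
"Country05","lang05",6.9316,-4.2707,0.5276,NA,0.5515,0.5808,0.5827,0.5927,8.4,16.7,53.3,2.1,19.5,0
"Country06","lang06",13.6057,35.5363,0.5057,0.5094,0.5278,0.53,0.5354,0.5638,41.4,37.8,15.3,0.4,5.1,1
"Country07","lang07",31.8314,11.189,0.4704,0.4637,0.5054,0.4996,0.4974,0.5203,35.8,14.3,34.3,5.5,10.1,0
"Country08","lang08",8.4131,21.287,0.6867,0.6804,0.6773,0.7141,0.6891,0.7311,22.7,32.5,12.9,21.1,10.8,1
"Country09","lang09",11.918,57.3367,0.434,0.4314,0.4686,0.4711,0.4902,0.4816,31.1,17.8,4.3,34.6,12.2,0
"Country10","lang10",31.9529,31.6312,0.3107,0.3251,0.3359,0.3455,0.3529,0.3748,29,6,31.9,13.4,19.7,1
"Country11","lang11",10.5081,29.1703,0.5494,0.5745,0.5623,0.5809,0.587,0.6103,11.5,25.4,27.1,17.2,18.8,0
"Country12","lang12",5.0081,41.1424,0.8808,0.8943,0.8875,0.897,0.9255,0.9255,37.5,2.4,15.7,12.8,31.6,1
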