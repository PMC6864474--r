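cultivar,species,n_plants,months,berries_present
Biloxi,V. corymbosum,1,December,NA
New hanover,V. corymbosum,1,May,NA
Camellia,V. corymbosum,2,May;September;December,NA
O'neal,V. corymbosum,1,May;December,NA
Misty,V. corymbosum,1,May;September;December,NA
Alix blue,V. corymbosum,1,May,NA
Star,V. corymbosum,1,May;December,NA
Gupton,V. corymbosum,1,May,NA
Cipria,V. corymbosum,1,May,NA
Goldtraube,V. corymbosum,1,May;September;December,NA
Legacy,V. corymbosum,2,May;September;December,NA
Ozarkblue,V. corymbosum,1,May;September,NA
Bluegold,V. corymbosum,1,May,NA
Draper,V. corymbosum,2,May;December,NA
Chandler,V. corymbosum,2,May;September;December,NA
Liberty,V. corymbosum,1,May;September;December,NA
Bluecrop,V. corymbosum,2,May;September;December,NA
Sunset blue,V. corymbosum,1,May,NA
Duke,V. corymbosum,2,May;September;December,NA
Patriot,V. corymbosum,1,December,NA
Bluejay,V. corymbosum,1,May,NA
Huron,V. corymbosum,1,May;September;December,NA
Aurora,V. corymbosum,1,May;September;December,NA
Elliott,V. corymbosum,1,December,NA
Titan,V. ashei,1,May;September;December,NA
Ochlochonee,V. ashei,2,May;September,NA
Powderblue,V. ashei,2,May;December,NA
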