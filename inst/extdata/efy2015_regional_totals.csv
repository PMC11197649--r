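region,element_code,value
Addis Ababa,i,23295
Addis Ababa,ii,153626
Addis Ababa,iii,190916
Addis Ababa,iv,44957
Addis Ababa,v,166583
Addis Ababa,vi,187518
Addis Ababa,vii,173853
Addis Ababa,viii,152684
Addis Ababa,ix,144678
Addis Ababa,x,142194
Addis Ababa,xi,139129
Addis Ababa,xii,138926
Addis Ababa,xiii,6188
Addis Ababa,xiv,12369
Addis Ababa,xv,84321
Addis Ababa,xvi,91895
Addis Ababa,xvii,2648
Addis Ababa,xviii,2829
Addis Ababa,xix,24942
Addis Ababa,xx,34914
Addis Ababa,xxi,15078
Addis Ababa,xxii,21132
Addis Ababa,xxiii,1700554
Addis Ababa,xxiv,4094391
Oromia,i,141120
Oromia,ii,1107606
Oromia,iii,1506219
Oromia,iv,332985
Oromia,v,1062412
Oromia,vi,1202867
Oromia,vii,1070449
Oromia,viii,1710910
Oromia,ix,1546208
Oromia,x,1466519
Oromia,xi,1512186
Oromia,xii,1429770
Oromia,xiii,43140
Oromia,xiv,92922
Oromia,xv,278635
Oromia,xvi,311931
Oromia,xvii,19216
Oromia,xviii,19834
Oromia,xix,244374
Oromia,xx,303406
Oromia,xxi,83226
Oromia,xxii,103163
Oromia,xxiii,11931264
Oromia,xxiv,18595369
Somali,i,3367
Somali,ii,82554
Somali,iii,203938
Somali,iv,39404
Somali,v,129593
Somali,vi,95392
Somali,vii,49095
Somali,viii,145813
Somali,ix,203460
Somali,x,180964
Somali,xi,199329
Somali,xii,179552
Somali,xiii,537
Somali,xiv,1999
Somali,xv,985
Somali,xvi,1203
Somali,xvii,1168
Somali,xviii,1326
Somali,xix,5217
Somali,xx,6507
Somali,xxi,2638
Somali,xxii,3264
Somali,xxiii,351440
Somali,xxiv,677852
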