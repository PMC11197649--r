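region,facility_type,element_code,value
Addis Ababa,health_centre,i,14311
Addis Ababa,health_centre,ii,55884
Addis Ababa,health_centre,iii,131318
Addis Ababa,health_centre,iv,33140
Addis Ababa,health_centre,v,105165
Addis Ababa,health_centre,vi,130997
Addis Ababa,health_centre,vii,129171
Addis Ababa,health_centre,viii,127992
Addis Ababa,health_centre,ix,116301
Addis Ababa,health_centre,x,117499
Addis Ababa,health_centre,xi,111966
Addis Ababa,health_centre,xii,114418
Addis Ababa,health_centre,xiii,3205
Addis Ababa,health_centre,xiv,4786
Addis Ababa,health_centre,xv,41790
Addis Ababa,health_centre,xvi,45027
Addis Ababa,health_centre,xvii,2286
Addis Ababa,health_centre,xviii,2418
Addis Ababa,health_centre,xix,18214
Addis Ababa,health_centre,xx,24041
Addis Ababa,health_centre,xxi,8012
Addis Ababa,health_centre,xxii,11220
Addis Ababa,health_centre,xxiii,1350937
Addis Ababa,health_centre,xxiv,2983719
Addis Ababa,public_hospital,i,7217
Addis Ababa,public_hospital,ii,64858
Addis Ababa,public_hospital,iii,12351
Addis Ababa,public_hospital,iv,1715
Addis Ababa,public_hospital,v,25712
Addis Ababa,public_hospital,vi,9305
Addis Ababa,public_hospital,vii,6276
Addis Ababa,public_hospital,viii,6715
Addis Ababa,public_hospital,ix,1474
Addis Ababa,public_hospital,x,1318
Addis Ababa,public_hospital,xi,1378
Addis Ababa,public_hospital,xii,1322
Addis Ababa,public_hospital,xiii,820
Addis Ababa,public_hospital,xiv,2037
Addis Ababa,public_hospital,xv,28351
Addis Ababa,public_hospital,xvi,30917
Addis Ababa,public_hospital,xvii,89
Addis Ababa,public_hospital,xviii,96
Addis Ababa,public_hospital,xix,5200
Addis Ababa,public_hospital,xx,8830
Addis Ababa,public_hospital,xxi,5663
Addis Ababa,public_hospital,xxii,8066
Addis Ababa,public_hospital,xxiii,297953
Addis Ababa,public_hospital,xxiv,1028499
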