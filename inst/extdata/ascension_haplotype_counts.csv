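short_hap,extended_hap,accession,mtstr_hap,count
CM-A6,CM-A6.1,JQ366073,7-12-4-4,5
CM-A6,CM-A6.1,JQ366073,Unidentified,2
CM-A8,CM-A8.1,JF308472,6-12-4-4,5
CM-A8,CM-A8.1,JF308472,6-13-4-4,9
CM-A8,CM-A8.1,JF308472,6-14-4-4,3
CM-A8,CM-A8.1,JF308472,6-17-4-4,3
CM-A8,CM-A8.1,JF308472,7-11-4-4,13
CM-A8,CM-A8.1,JF308472,7-12-4-4,85
CM-A8,CM-A8.1,JF308472,7-13-4-4,14
CM-A8,CM-A8.1,JF308472,7-14-4-4,1
CM-A8,CM-A8.1,JF308472,7-15-4-4,2
CM-A8,CM-A8.1,JF308472,7-16-4-4,6
CM-A8,CM-A8.1,JF308472,8-10-4-4,1
CM-A8,CM-A8.1,JF308472,8-11-4-4,7
CM-A8,CM-A8.1,JF308472,8-12-4-4,5
CM-A8,CM-A8.1,JF308472,8-13-4-4,1
CM-A8,CM-A8.1,JF308472,8-14-4-4,5
CM-A8,CM-A8.1,JF308472,8-15-4-4,1
CM-A8,CM-A8.1,JF308472,Unidentified,51
CM-A8,CM-A8.3,JF308474,7-11-4-4,2
CM-A8,CM-A8.3,JF308474,7-12-4-4,1
CM-A9,CM-A9.1,JF308475,7-11-4-4,3
CM-A9,CM-A9.1,JF308475,7-12-4-4,5
CM-A9,CM-A9.1,JF308475,Unidentified,2
CM-A10,CM-A10.1,JF308476,7-12-4-4,2
CM-A10,CM-A10.1,JF308476,7-17-4-4,1
CM-A10,CM-A10.1,JF308476,8-12-4-4,1
CM-A10,CM-A10.1,JF308476,Unidentified,5
CM-A24,CM-A24.1,JF308479,7-12-4-4,6
CM-A32,CM-A32.1,JF308480,7-12-4-4,1
CM-A32,CM-A32.1,JF308480,Unidentified,1
CM-A39,CM-A39.1,PQ604655,7-12-4-4,2
CM-A39,CM-A39.1,PQ604655,8-12-4-4,3
CM-A39,CM-A39.1,PQ604655,Unidentified,1
CM-A42,CM-A42.1,JF308481,6-17-4-4,1
CM-A42,CM-A42.1,JF308481,7-12-4-4,2
CM-A42,CM-A42.1,JF308481,Unidentified,1
CM-A45,CM-A45.1,PP429908,5-13-4-4,1
CM-A45,CM-A45.1,PP429908,5-14-4-4,1
CM-A45,CM-A45.1,PP429908,Unidentified,5
CM-A69,CM-A69.1,KC792574,7-12-4-4,1
NA,NA,,6-12-4-4,1
NA,NA,,7-12-4-4,2
NA,NA,,Unidentified,19
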