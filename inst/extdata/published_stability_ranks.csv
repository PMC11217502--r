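genotype,trait,rASI,rY,SSI
Dh 86,IOD15F,21,23,44
Dh 86,IOD21F,23,23,46
Dh 86,IOD15L,30,24,54
Dh 86,IOD21L,24,23,47
Girnar 3,IOD15F,3,21,24
Girnar 3,IOD21F,24,22,46
Girnar 3,IOD15L,1,19,20
Girnar 3,IOD21L,18,19,37
PBS 15044,IOD15F,12,11,23
PBS 15044,IOD21F,10,8,18
PBS 15044,IOD15L,8,16.5,24.5
PBS 15044,IOD21L,7,17,24
PBS 16004,IOD15F,11,5,16
PBS 16004,IOD21F,16,7,23
PBS 16004,IOD15L,15,4,19
PBS 16004,IOD21L,9,8,17
PBS 16013,IOD15F,14,6.5,20.5
PBS 16013,IOD21F,18,5,23
PBS 16013,IOD15L,2,14.5,16.5
PBS 16013,IOD21L,17,13,30
PBS 16015,IOD15F,6,2.5,8.5
PBS 16015,IOD21F,7,1.5,8.5
PBS 16015,IOD15L,12,4,16
PBS 16015,IOD21L,4,2,6
PBS 16016,IOD15F,9,8,17
PBS 16016,IOD21F,6,6,12
PBS 16016,IOD15L,14,4,18
PBS 16016,IOD21L,5,2,7
PBS 16017,IOD15F,2,9,11
PBS 16017,IOD21F,4,14,18
PBS 16017,IOD15L,17,8,25
PBS 16017,IOD21L,10,6.5,16.5
PBS 16020,IOD15F,17,10,27
PBS 16020,IOD21F,15,13,28
PBS 16020,IOD15L,16,16.5,32.5
PBS 16020,IOD21L,19,15,34
PBS 16021,IOD15F,5,2.5,7.5
PBS 16021,IOD21F,13,4,17
PBS 16021,IOD15L,11,4,15
PBS 16021,IOD21L,2,4,6
PBS 16024,IOD15F,30,22,52
PBS 16024,IOD21F,30,21,51
PBS 16024,IOD15L,24,20,44
PBS 16024,IOD21L,22,20,42
PBS 16025,IOD15F,26,29,55
PBS 16025,IOD21F,28,29,57
PBS 16025,IOD15L,26,28,54
PBS 16025,IOD21L,27,27,54
PBS 16026,IOD15F,4,14,18
PBS 16026,IOD21F,14,12,26
PBS 16026,IOD15L,7,9,16
PBS 16026,IOD21L,13,6.5,19.5
PBS 16027,IOD15F,24,28,52
PBS 16027,IOD21F,22,27,49
PBS 16027,IOD15L,18,29,47
PBS 16027,IOD21L,11,30.5,41.5
PBS 16028,IOD15F,16,32,48
PBS 16028,IOD21F,8,32,40
PBS 16028,IOD15L,6,31,37
PBS 16028,IOD21L,20,28,48
PBS 16029,IOD15F,29,30,59
PBS 16029,IOD21F,12,30,42
PBS 16029,IOD15L,22,30,52
PBS 16029,IOD21L,25,30.5,55.5
PBS 16031,IOD15F,22,13,35
PBS 16031,IOD21F,19,10,29
PBS 16031,IOD15L,9,4,13
PBS 16031,IOD21L,6,5,11
PBS 16032,IOD15F,28,26,54
PBS 16032,IOD21F,25,28,53
PBS 16032,IOD15L,29,27,56
PBS 16032,IOD21L,14,32,46
PBS 16035,IOD15F,1,16,17
PBS 16035,IOD21F,1,15,16
PBS 16035,IOD15L,20,11,31
PBS 16035,IOD21L,26,12,38
PBS 16037,IOD15F,15,6.5,21.5
PBS 16037,IOD21F,11,11,22
PBS 16037,IOD15L,13,4,17
PBS 16037,IOD21L,12,9,21
PBS 16038,IOD15F,19,12,31
PBS 16038,IOD21F,21,9,30
PBS 16038,IOD15L,4,12.5,16.5
PBS 16038,IOD21L,8,10,18
PBS 16039,IOD15F,23,15,38
PBS 16039,IOD21F,26,17,43
PBS 16039,IOD15L,23,14.5,37.5
PBS 16039,IOD21L,23,14,37
PBS 16041,IOD15F,7,2.5,9.5
PBS 16041,IOD21F,9,1.5,10.5
PBS 16041,IOD15L,10,4,14
PBS 16041,IOD21L,3,2,5
PBS 16042,IOD15F,10,18,28
PBS 16042,IOD21F,20,18,38
PBS 16042,IOD15L,3,12.5,15.5
PBS 16042,IOD21L,1,16,17
PBS 16044,IOD15F,13,31,44
PBS 16044,IOD21F,3,31,34
PBS 16044,IOD15L,27,32,59
PBS 16044,IOD21L,21,29,50
PBS 16045,IOD15F,8,2.5,10.5
PBS 16045,IOD21F,5,3,8
PBS 16045,IOD15L,5,10,15
PBS 16045,IOD21L,15,11,26
PBS 16046,IOD15F,25,20,45
PBS 16046,IOD21F,2,20,22
PBS 16046,IOD15L,28,22,50
PBS 16046,IOD21L,32,21,53
PBS 16047,IOD15F,31,25,56
PBS 16047,IOD21F,31,25,56
PBS 16047,IOD15L,25,26,51
PBS 16047,IOD21L,28,25,53
PBS 16051,IOD15F,27,24,51
PBS 16051,IOD21F,29,24,53
PBS 16051,IOD15L,32,23,55
PBS 16051,IOD21L,31,24,55
PBS 16052,IOD15F,32,27,59
PBS 16052,IOD21F,32,26,58
PBS 16052,IOD15L,31,25,56
PBS 16052,IOD21L,29,26,55
PBS 16053,IOD15F,20,19,39
PBS 16053,IOD21F,27,19,46
PBS 16053,IOD15L,19,21,40
PBS 16053,IOD21L,30,22,52
TPG 41,IOD15F,18,17,35
TPG 41,IOD21F,17,16,33
TPG 41,IOD15L,21,18,39
TPG 41,IOD21L,16,18,34
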