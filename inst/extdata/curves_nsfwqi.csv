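parameter,x,q
do_sat,0,2
do_sat,10,7
do_sat,20,12
do_sat,30,18
do_sat,40,25
do_sat,50,33
do_sat,60,45
do_sat,70,57
do_sat,80,75
do_sat,90,88
do_sat,100,98
do_sat,110,95
do_sat,120,82
do_sat,130,63
do_sat,140,50
fecal_coliform,0,100
fecal_coliform,1,98
fecal_coliform,10,72
fecal_coliform,50,52
fecal_coliform,100,43
fecal_coliform,500,26
fecal_coliform,1000,22
fecal_coliform,10000,8
fecal_coliform,100000,2
bod5,0,98
bod5,1,90
bod5,2,80
bod5,3,70
bod5,4,62
bod5,5,55
bod5,6,49
bod5,8,38
bod5,10,32
bod5,15,22
bod5,20,15
bod5,30,9
no3,0,98
no3,5,76
no3,10,58
no3,20,43
no3,30,35
no3,40,28
no3,50,23
no3,100,2
po4,0,99
po4,0.25,80
po4,0.5,60
po4,0.75,50
po4,1,39
po4,2,28
po4,3,22
po4,4,18
po4,6,13
po4,10,5
turbidity,0,97
turbidity,5,84
turbidity,10,76
turbidity,20,62
turbidity,30,53
turbidity,40,45
turbidity,50,39
turbidity,70,28
turbidity,100,8
ph,2,0
ph,3,4
ph,4,11
ph,5,30
ph,6,55
ph,6.5,75
ph,7,88
ph,7.5,93
ph,8,84
ph,8.5,67
ph,9,47
ph,10,19
ph,11,7
ph,12,2
temperature,0,40
temperature,5,60
temperature,10,85
temperature,15,93
temperature,20,72
temperature,25,50
temperature,30,30
temperature,35,15
ts,0,80
ts,50,86
ts,100,82
ts,150,78
ts,200,73
ts,300,62
ts,400,52
ts,500,32
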