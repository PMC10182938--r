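parameter,x,q
fecal_coliform,0,100
fecal_coliform,1,95
fecal_coliform,10,70
fecal_coliform,50,50
fecal_coliform,100,40
fecal_coliform,500,25
fecal_coliform,1000,20
fecal_coliform,5000,10
fecal_coliform,100000,1
bod5,0,99
bod5,2,80
bod5,4,60
bod5,6,48
bod5,8,38
bod5,10,32
bod5,15,22
bod5,20,15
bod5,30,9
bod5,100,1
cod,0,98
cod,5,85
cod,10,70
cod,20,50
cod,30,35
cod,50,20
cod,100,8
cod,200,1
no3,0,97
no3,5,75
no3,10,57
no3,20,42
no3,30,34
no3,40,27
no3,50,22
no3,100,1
do_sat,0,1
do_sat,10,5
do_sat,20,10
do_sat,30,17
do_sat,40,25
do_sat,50,34
do_sat,60,45
do_sat,70,58
do_sat,80,75
do_sat,90,88
do_sat,100,97
do_sat,120,80
do_sat,140,45
ec,0,98
ec,250,85
ec,500,70
ec,750,55
ec,1000,45
ec,1500,30
ec,2500,15
ec,5000,5
ec,10000,1
nh4,0,98
nh4,0.2,85
nh4,0.5,65
nh4,1,45
nh4,2,30
nh4,5,15
nh4,10,5
nh4,25,1
po4,0,98
po4,0.25,80
po4,0.5,60
po4,1,40
po4,2,28
po4,4,18
po4,6,12
po4,10,5
po4,20,1
turbidity,0,96
turbidity,5,84
turbidity,10,75
turbidity,20,60
turbidity,30,50
turbidity,40,43
turbidity,50,37
turbidity,70,27
turbidity,100,10
turbidity,200,1
th,0,90
th,50,95
th,150,80
th,250,65
th,350,50
th,500,35
th,750,20
th,1000,10
th,2000,1
ph,2,1
ph,4,10
ph,5,30
ph,6,55
ph,7,88
ph,7.5,92
ph,8,84
ph,9,45
ph,10,18
ph,12,1
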