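site_id,pair_id,island_type,area_m2
C01,1,colony,300
C02,2,colony,500
C03,3,colony,700
C04,4,colony,900
C05,5,colony,1100
C06,6,colony,1300
C07,7,colony,1500
C08,8,colony,1700
C09,9,colony,1900
C10,10,colony,2100
C11,11,colony,2300
C12,12,colony,2500
C13,13,colony,2700
C14,14,colony,2900
C15,15,colony,3100
X01,1,control,280
X02,2,control,474.285714285714
X03,3,control,668.571428571429
X04,4,control,862.857142857143
X05,5,control,1057.14285714286
X06,6,control,1251.42857142857
X07,7,control,1445.71428571429
X08,8,control,1640
X09,9,control,1834.28571428571
X10,10,control,2028.57142857143
X11,11,control,2222.85714285714
X12,12,control,2417.14285714286
X13,13,control,2611.42857142857
X14,14,control,2805.71428571429
X15,15,control,3000
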