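# silver_synthetic (attenuation), 60 bins [keV]
10.583333333333334 528.89896146054195
11.75 394.68581234594222
12.916666666666668 302.82126450932498
14.083333333333334 237.73399082058219
15.25 190.27397898707082
16.416666666666668 154.81587853022765
17.583333333333336 127.76715871636208
18.75 106.75777892820449
19.916666666666668 90.179704231515245
21.083333333333336 76.914864337471187
22.25 66.168919813103258
23.416666666666668 57.366626782756917
24.583333333333336 50.084223559491015
25.75 219.42352989427715
26.916666666666668 193.83807722146989
28.083333333333336 172.14120052206007
29.25 153.61524048482477
30.416666666666668 137.69662227211097
31.583333333333336 123.93846067614048
32.75 111.983214763037
33.916666666666671 101.54244702974269
35.083333333333336 92.381672069206701
36.25 84.308896223437131
37.416666666666671 77.165864650807947
38.583333333333336 70.821315505437639
39.75 65.165736867623664
40.916666666666671 60.107259271663658
42.083333333333336 55.568413865169951
43.25 51.483555818944424
44.416666666666671 47.796802933841413
45.583333333333336 44.460376137796608
46.75 41.433255638383152
47.916666666666671 38.680086610345363
49.083333333333336 36.170283361941003
50.25 33.877292292156071
51.416666666666671 31.77798259170466
52.583333333333336 29.85214025352402
53.75 28.082046052195174
54.916666666666671 26.452122099667221
56.083333333333336 24.948634662666073
57.25 23.559443340474196
58.416666666666671 22.27378860412384
59.583333333333336 21.082111205369959
60.75 19.975898164031324
61.916666666666671 18.947551002501207
63.083333333333336 17.990272667915423
64.25 17.097970205344922
65.416666666666671 16.265170750251567
66.583333333333343 15.486948819315266
67.75 14.758863214406123
68.916666666666671 14.076902129724665
70.083333333333343 13.437435278652877
71.25 12.837172043921525
72.416666666666671 12.273124809695783
73.583333333333343 11.74257676302236
74.75 11.243053559515459
75.916666666666671 10.772298338013311
77.083333333333343 10.328249644307347
78.25 9.9090218874456877
79.416666666666671 9.5128880055889109
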