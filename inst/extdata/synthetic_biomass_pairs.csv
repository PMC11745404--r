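cover,agb,region
69.6,79.95,NAm
45.2,30.19,NAm
48.9,34.67,NAm
47.4,30.91,NAm
74.1,96.43,NAm
47.9,36.12,Eurasia
85.3,152.96,Eurasia
12.1,10.36,Eurasia
61.2,59.04,Eurasia
54.1,46.62,Eurasia
41.4,26.75,NAm
90.5,190.5,NAm
62.2,59.99,NAm
2.3,5.29,NAm
44.5,27.91,NAm
81.4,126.31,NAm
34.7,20.35,Eurasia
34.7,19.57,NAm
72.1,85.98,Eurasia
10.2,9.23,NAm
32.9,20.76,NAm
77.4,112.56,NAm
3.8,6.2,Eurasia
68,77.88,Eurasia
32,22.48,NAm
87.2,165.99,NAm
73.9,94.78,Eurasia
18.9,12.44,Eurasia
81.4,126.11,Eurasia
24.7,11.39,Eurasia
40.2,26.04,Eurasia
13.6,10.39,NAm
45.5,33.74,Eurasia
51.8,40.94,Eurasia
62.9,58.86,NAm
10.8,5.56,Eurasia
9,8.44,Eurasia
16.8,10.65,NAm
94.3,219.02,NAm
86,155.37,Eurasia
38.3,23.98,NAm
88.4,172.99,NAm
73,94.73,Eurasia
77.4,111.11,Eurasia
94.8,222.36,Eurasia
77.3,111.01,Eurasia
71.2,88.75,Eurasia
12.5,10.99,Eurasia
43.1,28.59,NAm
51.4,39.2,Eurasia
9.2,6.83,NAm
69.9,76.2,NAm
17,8.46,NAm
12.5,8.06,NAm
49.4,35.72,NAm
34.1,17.53,NAm
33.4,15.38,NAm
56.1,49.61,Eurasia
72.7,89.22,NAm
57.1,50.78,Eurasia
14.5,11.25,NAm
70.5,83.68,NAm
91.7,198.2,Eurasia
20.7,10.03,Eurasia
9.7,8.04,Eurasia
72.9,94.76,NAm
68.6,79.02,Eurasia
31.6,18.85,Eurasia
25,13.43,NAm
17.7,11.98,Eurasia
9.8,7.62,Eurasia
94.6,219.19,Eurasia
58.1,51.55,NAm
40.9,25.92,NAm
6.6,5.66,Eurasia
47.1,33.25,NAm
77.8,110.61,Eurasia
57.5,50.48,NAm
79.3,118.94,Eurasia
56,46.36,NAm
85.4,153.41,Eurasia
20.7,6.97,Eurasia
88.2,171.55,NAm
8.1,5.59,NAm
25.7,11.81,NAm
33.1,17.26,Eurasia
34.1,16.96,Eurasia
18.3,11.77,Eurasia
6,6.93,Eurasia
49.2,36.94,NAm
82.8,137.42,NAm
89.9,181.45,Eurasia
31.3,20.49,NAm
86.1,156.03,Eurasia
52.4,38.99,NAm
63.1,61.54,Eurasia
76.8,109.6,Eurasia
75.3,102.56,Eurasia
65.9,66.16,NAm
25.7,17.75,Eurasia
61.2,59.21,NAm
91.5,195.51,NAm
10.4,8.65,Eurasia
76.8,109.71,Eurasia
41.4,25.23,NAm
76.4,110.42,Eurasia
81.9,131.11,NAm
41.2,26.91,NAm
60.8,58.03,Eurasia
88.3,174.17,NAm
81.4,129.26,NAm
13,8.7,NAm
69.8,80.5,Eurasia
76.7,102.25,Eurasia
19.3,8.23,NAm
11.4,12.87,NAm
23.2,15.22,Eurasia
68,75.68,NAm
45.8,33.26,NAm
15.8,9.79,NAm
68.8,77.63,NAm
63.2,62.87,Eurasia
70.2,81.78,NAm
52.6,42.66,NAm
65,64.55,Eurasia
68.1,75.48,NAm
86.9,162.27,NAm
85.4,154.02,Eurasia
11.9,10.23,Eurasia
68.6,75.91,Eurasia
0.7,5.18,NAm
63.6,62.41,Eurasia
17.4,11.94,Eurasia
41.4,24.15,NAm
32.8,17.45,Eurasia
57.8,53.22,NAm
90.9,186.65,Eurasia
12.7,8.96,Eurasia
32.4,18.15,NAm
68.4,74.63,Eurasia
44,27.04,NAm
87.2,162.77,Eurasia
21.6,14.25,NAm
91.2,192.44,Eurasia
19.5,8.63,NAm
64.6,67.71,NAm
1,6.58,Eurasia
31.9,17.62,NAm
28.1,14.6,NAm
70,85.19,NAm
79.9,120.38,NAm
83.4,139.86,Eurasia
27.8,15.39,NAm
81.2,126.63,NAm
88.8,172.47,NAm
38.4,22.94,NAm
21.7,14.88,Eurasia
1.1,0.3,NAm
24,11.39,Eurasia
79.5,122.13,Eurasia
12.5,10.17,NAm
32.4,16.27,Eurasia
88.3,171.93,Eurasia
23.9,13.56,Eurasia
55.2,42.5,Eurasia
86.1,157.48,NAm
13.7,10.95,NAm
13.2,6.19,NAm
47.5,32.05,Eurasia
50.5,41.3,NAm
46.6,34.38,NAm
52.2,41.53,NAm
85.9,155.18,NAm
72.3,89.12,Eurasia
15.3,10.49,Eurasia
61.1,57.51,NAm
14,7.99,NAm
9.6,8.26,NAm
80.1,125.33,Eurasia
38.9,19.04,NAm
69.8,76.94,NAm
84.7,147.05,Eurasia
17.4,11.07,Eurasia
86.1,155.07,NAm
90.9,192.97,Eurasia
70.4,84.09,Eurasia
50.9,36.27,NAm
90.6,187.9,NAm
31.8,18.13,NAm
21.9,10.01,Eurasia
13.9,9.5,NAm
83.8,146.73,Eurasia
3.1,5.42,Eurasia
55.3,44.73,Eurasia
6.4,6.49,Eurasia
86.5,159.65,NAm
19.5,11.75,Eurasia
0.4,3.46,Eurasia
55.6,44.88,Eurasia
19.1,12.12,NAm
71.7,89.16,Eurasia
3.6,5.82,NAm
37.9,17.66,Eurasia
17.1,11.72,NAm
80.9,126.96,NAm
84.9,146.81,Eurasia
56.4,47.97,NAm
44.5,29.99,NAm
8.8,12.78,Eurasia
60.3,54.35,NAm
44.6,32.55,NAm
88,167.56,Eurasia
9.8,6.93,NAm
80,121.48,NAm
88.7,172.8,Eurasia
87.5,166.57,Eurasia
60,53.46,NAm
19.3,11.53,Eurasia
84.5,145.18,Eurasia
62.8,62.55,NAm
11,8.19,NAm
31.2,16.81,NAm
31.6,17.61,NAm
49.5,39.91,NAm
35.9,23.18,Eurasia
20.1,10.52,NAm
2.7,7.98,NAm
53.4,43.46,Eurasia
42.2,26.79,NAm
2.1,4.83,Eurasia
83.3,136.54,NAm
3.4,5.91,NAm
6.4,6.1,Eurasia
94.6,220.47,NAm
45.7,33.49,Eurasia
91.6,192.64,Eurasia
39.2,27.35,Eurasia
1.9,1.72,NAm
34.7,19.09,Eurasia
52.1,38.58,Eurasia
24.8,10.64,NAm
28.2,16.78,Eurasia
18.4,10.6,Eurasia
83.8,143.17,NAm
31.7,15.09,NAm
26.1,14,NAm
7.8,6.54,NAm
3.6,6.58,NAm
56.9,49.07,NAm
58.1,50.26,NAm
45.8,31.32,Eurasia
90.2,182.83,NAm
8,5.3,Eurasia
73,93.87,NAm
45.3,34.18,Eurasia
60.1,57.08,NAm
4,6.05,Eurasia
14,9.45,NAm
42.5,30.05,NAm
50,35.74,NAm
73.8,96.41,NAm
47.8,33.39,Eurasia
45.5,30.87,NAm
27.5,12.08,Eurasia
22.5,10.13,NAm
20.5,10.32,NAm
8.4,12.34,Eurasia
63.5,61.55,Eurasia
14.7,9.57,NAm
39.8,25.1,Eurasia
89.4,180.03,NAm
44.8,28.31,Eurasia
14.8,8.72,Eurasia
28.4,16.38,NAm
43.8,29.8,Eurasia
78.8,117.68,Eurasia
14.2,7.22,NAm
90.4,184.83,Eurasia
78.5,116.14,Eurasia
39,24.29,NAm
23.5,10.5,Eurasia
83.9,145.66,NAm
2.6,4.95,NAm
42.5,25.72,Eurasia
78.4,117.69,Eurasia
70.3,81.83,Eurasia
70,79.68,NAm
54.2,42.05,Eurasia
35.6,17.51,NAm
27.1,16.86,NAm
25.9,15.26,NAm
85,150.81,Eurasia
9.8,7.43,Eurasia
46.6,35.02,Eurasia
80.4,122.9,NAm
89.9,181.23,Eurasia
64.7,66.95,NAm
50.6,38.78,NAm
50.5,39.26,Eurasia
66.7,76.26,NAm
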