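# SWC written by neuromesh
1 1 0 0 0 5 -1
2 2 4.7828 -0.8547 3.0751 0.8 1
3 2 9.4365 -1.6318 5.6192 0.6928 2
4 2 13.0572 -2.2113 8.0242 0.6051 3
5 2 18.6645 -2.7213 11.3862 0.4739 4
6 2 21.039 -3.2902 16.2574 0.2939 5
7 2 23.8541 -3.9416 21.507 0.174 6
8 2 26.6507 -4.8473 26.4454 0.08 7
9 2 24.9327 -3.0248 10.9273 0.277 5
10 2 29.659 -3.4448 10.7324 0.182 9
11 2 35.8034 -3.9933 10.4316 0.08 10
12 3 -3.8411 3.9816 1.5671 0.8 1
13 3 -7.5217 8.1882 2.9241 0.685 12
14 3 -11.1965 12.1764 4.1072 0.5739 13
15 3 -13.6666 15.2374 5.0014 0.4933 14
16 3 -15.5477 20.3828 6.0894 0.3076 15
17 3 -16.8184 24.3213 6.6083 0.2242 16
18 3 -18.6365 30.4718 7.6612 0.0942 17
19 3 -18.4464 18.3843 6.4056 0.3014 15
20 3 -23.7429 21.8589 7.8653 0.1714 19
21 3 -28.8872 25.7001 9.5213 0.08 20
22 3 -0.2748 -5.4047 -1.9433 0.8 1
23 3 -0.1214 -9.2682 -3.5889 0.716 22
24 3 0.1498 -15.7892 -6.6162 0.5721 23
25 3 0.4962 -21.314 -8.9482 0.4519 24
26 3 0.7609 -28.4224 -9.5489 0.2414 25
27 3 1.6192 -35.2533 -9.6808 0.1036 26
28 3 2.5953 -42.1358 -10.0053 0.08 27
29 3 1.0922 -26.787 -14.0013 0.2347 25
30 3 1.6718 -30.7557 -17.8229 0.1239 29
31 3 1.7094 -33.9688 -20.9452 0.08 30
32 3 2.599 2.9394 -4.2033 0.8 1
33 3 4.8751 5.7362 -7.8946 0.6968 32
34 3 7.8284 10.0456 -12.43 0.5584 33
35 3 10.3672 13.5996 -15.8495 0.4475 34
36 3 13.9993 16.7025 -21.9739 0.225 35
37 3 16.6362 18.7776 -25.8413 0.1226 36
38 3 18.8472 20.4158 -29.1253 0.08 37
39 3 12.7909 17.8692 -17.4733 0.2769 35
40 3 15.2489 21.9232 -18.7035 0.179 39
41 3 18.3923 26.3003 -20.3727 0.08 40
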