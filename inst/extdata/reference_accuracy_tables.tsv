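table	participant	column	value
1	1	k1	0.74
1	1	k2	0.71
1	1	k3	0.79
1	1	k4	0.80
1	1	k5	0.86
1	2	k1	0.74
1	2	k2	0.69
1	2	k3	0.85
1	2	k4	0.89
1	2	k5	0.93
1	3	k1	0.84
1	3	k2	0.80
1	3	k3	0.84
1	3	k4	0.92
1	3	k5	0.91
1	4	k1	0.74
1	4	k2	0.69
1	4	k3	0.79
1	4	k4	0.83
1	4	k5	0.91
1	5	k1	0.90
1	5	k2	0.88
1	5	k3	0.92
1	5	k4	0.91
1	5	k5	0.93
1	6	k1	0.86
1	6	k2	0.83
1	6	k3	0.87
1	6	k4	0.96
1	6	k5	0.93
1	7	k1	0.87
1	7	k2	0.87
1	7	k3	0.90
1	7	k4	0.96
1	7	k5	0.92
2	1	k1	0.66
2	1	k2	0.67
2	1	k3	0.62
2	1	k4	0.74
2	1	k5	0.78
2	2	k1	0.65
2	2	k2	0.68
2	2	k3	0.64
2	2	k4	0.73
2	2	k5	0.59
2	3	k1	0.65
2	3	k2	0.57
2	3	k3	0.62
2	3	k4	0.63
2	3	k5	0.71
2	4	k1	0.63
2	4	k2	0.63
2	4	k3	0.64
2	4	k4	0.69
2	4	k5	0.65
2	5	k1	0.81
2	5	k2	0.80
2	5	k3	0.88
2	5	k4	0.93
2	5	k5	0.92
2	6	k1	0.73
2	6	k2	0.71
2	6	k3	0.72
2	6	k4	0.78
2	6	k5	0.70
2	7	k1	0.72
2	7	k2	0.65
2	7	k3	0.78
2	7	k4	0.74
2	7	k5	0.74
2	8	k1	0.71
2	8	k2	0.73
2	8	k3	0.71
2	8	k4	0.77
2	8	k5	0.83
2	9	k1	0.67
2	9	k2	0.63
2	9	k3	0.64
2	9	k4	0.73
2	9	k5	0.69
2	10	k1	0.72
2	10	k2	0.72
2	10	k3	0.77
2	10	k4	0.85
2	10	k5	0.83
3	1	k1	0.63
3	1	k2	0.67
3	1	k3	0.64
3	1	k4	0.72
3	1	k5	0.68
3	2	k1	0.63
3	2	k2	0.64
3	2	k3	0.62
3	2	k4	0.74
3	2	k5	0.64
3	3	k1	0.60
3	3	k2	0.47
3	3	k3	0.60
3	3	k4	0.60
3	3	k5	0.66
3	4	k1	0.61
3	4	k2	0.64
3	4	k3	0.63
3	4	k4	0.62
3	4	k5	0.54
3	5	k1	0.80
3	5	k2	0.76
3	5	k3	0.86
3	5	k4	0.81
3	5	k5	0.90
3	6	k1	0.69
3	6	k2	0.71
3	6	k3	0.71
3	6	k4	0.78
3	6	k5	0.75
3	7	k1	0.69
3	7	k2	0.61
3	7	k3	0.82
3	7	k4	0.71
3	7	k5	0.79
3	8	k1	0.73
3	8	k2	0.70
3	8	k3	0.72
3	8	k4	0.75
3	8	k5	0.83
3	9	k1	0.66
3	9	k2	0.59
3	9	k3	0.73
3	9	k4	0.67
3	9	k5	0.64
3	10	k1	0.73
3	10	k2	0.74
3	10	k3	0.77
3	10	k4	0.83
3	10	k5	0.78
4	1	k1	0.66
4	1	k2	0.61
4	1	k3	0.62
4	1	k4	0.76
4	1	k5	0.76
4	2	k1	0.59
4	2	k2	0.61
4	2	k3	0.64
4	2	k4	0.65
4	2	k5	0.52
4	3	k1	0.53
4	3	k2	0.44
4	3	k3	0.43
4	3	k4	0.47
4	3	k5	0.58
4	4	k1	0.54
4	4	k2	0.54
4	4	k3	0.58
4	4	k4	0.53
4	4	k5	0.33
4	5	k1	0.62
4	5	k2	0.56
4	5	k3	0.62
4	5	k4	0.73
4	5	k5	0.78
4	6	k1	0.56
4	6	k2	0.57
4	6	k3	0.63
4	6	k4	0.65
4	6	k5	0.47
4	7	k1	0.58
4	7	k2	0.59
4	7	k3	0.66
4	7	k4	0.61
4	7	k5	0.67
4	8	k1	0.56
4	8	k2	0.47
4	8	k3	0.51
4	8	k4	0.52
4	8	k5	0.57
4	9	k1	0.57
4	9	k2	0.49
4	9	k3	0.59
4	9	k4	0.43
4	9	k5	0.55
4	10	k1	0.73
4	10	k2	0.49
4	10	k3	0.59
4	10	k4	0.43
4	10	k5	0.55
5	1	first_k1	0.55
5	1	first_k4	0.48
5	1	latter_k1	0.72
5	1	latter_k4	0.63
5	2	first_k1	0.83
5	2	first_k4	0.92
5	2	latter_k1	0.77
5	2	latter_k4	0.81
5	3	first_k1	0.69
5	3	first_k4	0.83
5	3	latter_k1	0.64
5	3	latter_k4	0.58
5	4	first_k1	0.70
5	4	first_k4	0.56
5	4	latter_k1	0.70
5	4	latter_k4	0.78
5	5	first_k1	0.84
5	5	first_k4	1.00
5	5	latter_k1	0.73
5	5	latter_k4	0.92
5	6	first_k1	0.79
5	6	first_k4	0.92
5	6	latter_k1	0.63
5	6	latter_k4	0.92
5	7	first_k1	0.83
5	7	first_k4	0.58
5	7	latter_k1	0.64
5	7	latter_k4	0.75
6	1	first_k1	0.73
6	1	first_k4	0.89
6	1	latter_k1	0.64
6	1	latter_k4	0.70
6	2	first_k1	0.78
6	2	first_k4	0.80
6	2	latter_k1	0.63
6	2	latter_k4	0.52
6	3	first_k1	0.65
6	3	first_k4	0.73
6	3	latter_k1	0.73
6	3	latter_k4	0.72
6	4	first_k1	0.74
6	4	first_k4	0.83
6	4	latter_k1	0.60
6	4	latter_k4	0.62
6	5	first_k1	0.87
6	5	first_k4	0.92
6	5	latter_k1	0.82
6	5	latter_k4	0.80
6	6	first_k1	0.83
6	6	first_k4	0.94
6	6	latter_k1	0.66
6	6	latter_k4	0.70
6	7	first_k1	0.75
6	7	first_k4	0.83
6	7	latter_k1	0.70
6	7	latter_k4	0.70
6	8	first_k1	0.87
6	8	first_k4	0.86
6	8	latter_k1	0.72
6	8	latter_k4	0.80
6	9	first_k1	0.78
6	9	first_k4	0.91
6	9	latter_k1	0.67
6	9	latter_k4	0.66
6	10	first_k1	0.90
6	10	first_k4	0.97
6	10	latter_k1	0.74
6	10	latter_k4	0.84
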