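A C D E F G H I K L M N P Q R S T V W Y
3079 68 59 52 54 51 49 54 56 60 66 74 73 63 55 57 52 50 49 55
68 3076 65 56 57 52 48 52 52 54 58 63 72 70 60 61 54 50 47 52
59 65 3073 62 62 55 49 51 49 49 51 54 62 69 67 67 58 52 47 50
52 56 62 3070 69 59 51 53 49 46 46 47 54 59 66 74 64 55 48 50
54 57 62 69 3078 67 58 60 54 51 49 49 56 60 65 74 73 63 55 57
51 52 55 59 67 3076 65 65 57 52 48 46 51 53 57 64 71 70 60 61
49 48 49 51 58 65 3073 72 62 54 49 45 49 48 50 56 61 68 67 67
54 52 51 53 60 65 72 3081 70 61 54 49 53 51 52 58 62 68 76 75
56 52 49 49 54 57 62 70 3079 68 59 51 54 50 49 54 56 59 65 74
60 54 49 46 51 52 54 61 68 3076 65 56 57 51 48 51 51 53 56 64
66 58 51 46 49 48 49 54 59 65 3073 61 62 54 48 51 48 48 50 56
74 63 54 47 49 46 45 49 51 56 61 3069 68 58 51 52 48 45 45 50
73 72 62 54 56 51 49 53 54 57 62 68 3078 67 58 59 53 50 48 53
63 70 69 59 60 53 48 51 50 51 54 58 67 3075 64 64 56 50 47 51
55 60 67 66 65 57 50 52 49 48 48 51 58 64 3072 70 61 53 47 50
57 61 67 74 74 64 56 58 54 51 51 52 59 64 70 3079 69 60 53 55
52 54 58 64 73 71 61 62 56 51 48 48 53 56 61 69 3077 66 57 59
50 50 52 55 63 70 68 68 59 53 48 45 50 50 53 60 66 3074 63 63
49 47 47 48 55 60 67 76 65 56 50 45 48 47 47 53 57 63 3071 70
55 52 50 50 57 61 67 75 74 64 56 50 53 51 50 55 59 63 70 3080
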