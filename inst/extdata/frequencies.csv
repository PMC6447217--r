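label,per_day
never,0
1-3 per month,0.0657030223390276
once a week,0.142857142857142857
2-3 per week,0.357142857142857143
4-6 per week,0.714285714285714286
once a day,1
2-3 per day,2.5
4+ per day,4
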