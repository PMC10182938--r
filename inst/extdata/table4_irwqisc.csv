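station,period,score,label
1,Spring,39.23,Relatively bad
1,Summer,32.18,Relatively bad
1,Fall,33.17,Relatively bad
1,Winter,33.83,Relatively bad
1,Mean,34.7,Relatively bad
2,Spring,36.56,Relatively bad
2,Summer,32.03,Relatively bad
2,Fall,32.52,Relatively bad
2,Winter,34.37,Relatively bad
2,Mean,33.9,Relatively bad
3,Spring,36.83,Relatively bad
3,Summer,31.87,Relatively bad
3,Fall,32.76,Relatively bad
3,Winter,34.44,Relatively bad
3,Mean,34,Relatively bad
4,Spring,21.92,Bad
4,Summer,19.27,Bad
4,Fall,20.9,Bad
4,Winter,20.53,Bad
4,Mean,20.7,Bad
5,Spring,37.4,Relatively bad
5,Summer,32.34,Relatively bad
5,Fall,31.55,Relatively bad
5,Winter,34.04,Relatively bad
5,Mean,33.8,Relatively bad
Mean,Spring,34.4,Relatively bad
Mean,Summer,29.5,Bad
Mean,Fall,30.2,Relatively bad
Mean,Winter,31.4,Relatively bad
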