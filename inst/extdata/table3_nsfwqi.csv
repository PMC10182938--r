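station,period,score,label
1,Spring,49.32,Bad
1,Summer,43.05,Bad
1,Fall,29.4,Bad
1,Winter,44.38,Bad
1,Mean,41.5,Bad
2,Spring,44.21,Bad
2,Summer,39.13,Bad
2,Fall,39.54,Bad
2,Winter,46.52,Bad
2,Mean,42.3,Bad
3,Spring,47.22,Bad
3,Summer,40.72,Bad
3,Fall,43.51,Bad
3,Winter,45.67,Bad
3,Mean,44.2,Bad
4,Spring,33.82,Bad
4,Summer,32.61,Bad
4,Fall,33.9,Bad
4,Winter,33.41,Bad
4,Mean,33.4,Bad
5,Spring,42.93,Bad
5,Summer,38.79,Bad
5,Fall,36.46,Bad
5,Winter,42.6,Bad
5,Mean,40.2,Bad
Mean,Spring,43.5,Bad
Mean,Summer,38.9,Bad
Mean,Fall,36.6,Bad
Mean,Winter,42.5,Bad
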