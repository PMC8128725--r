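2019-02-04T08:01:00
2019-02-04T08:09:30
2019-02-04T08:17:12
2019-02-04T08:31:45
2019-02-04T08:44:02
2019-02-04T09:02:10
2019-02-04T09:15:33
2019-02-04T09:21:40
2019-02-04T12:40:00
2019-02-04T12:52:30
2019-02-04T13:05:11
2019-02-04T13:30:00
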