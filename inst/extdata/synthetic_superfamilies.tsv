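1abcA	a.1.1
1abcA	b.2.4
2defB	a.1.1
3ghiA	c.3.7
4jklC	a.1.1
5mnoB	c.3.7
6pqrA	d.9.2
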