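"date","value"
"2011-01",25016.6666666667
"2011-02",26766.6666666667
"2011-03",27616.6666666667
"2011-04",27966.6666666667
"2011-05",28316.6666666667
"2011-06",28566.6666666667
"2011-07",28816.6666666667
"2011-08",29066.6666666667
"2011-09",29416.6666666667
"2011-10",29866.6666666667
"2011-11",30716.6666666667
"2011-12",33766.6666666667
"2012-01",26816.6666666667
"2012-02",29628.2589555545
"2012-03",30302.016644762
"2012-04",30212.5708281016
"2012-05",30982.4570826993
"2012-06",30274.2467863591
"2012-07",31921.0435149534
"2012-08",31719.9947617235
"2012-09",33244.2979953376
"2012-10",33216.8330556817
"2012-11",33226.656310504
"2012-12",36834.291418399
"2013-01",30273.9730001794
"2013-02",33134.8567374712
"2013-03",33650.4320944023
"2013-04",33791.712192337
"2013-05",35113.0955476273
"2013-06",32553.6498668976
"2013-07",34877.6780719583
"2013-08",35175.2417613544
"2013-09",36072.0336728132
"2013-10",35323.0557773264
"2013-11",34605.4876023079
"2013-12",38284.6024372916
"2014-01",27636.3855514716
"2014-02",28679.0310949911
"2014-03",28038.4480905057
"2014-04",26794.444449559
"2014-05",26351.8378515107
"2014-06",23366.3185594093
"2014-07",23633.6063280589
"2014-08",22452.1184568154
"2014-09",22571.7527237083
"2014-10",20105.5863040496
"2014-11",17730.4643436758
"2014-12",20410.0720778624
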