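station_id,year,sown_date,emergence_date,anthesis_date,maturity_date,observed_yield,observed_duration
SYNCAL01,2005,2005-04-10,2005-04-28,,2005-08-28,6450,122
SYNCAL01,2006,2006-04-10,2006-04-30,,2006-09-02,6120,125
SYNCAL02,2009,2009-04-20,2009-05-08,2009-07-02,2009-09-05,5480,120
SYNCAL02,2010,2010-04-20,2010-05-11,2010-07-06,2010-09-10,5725,122
SYNCAL03,2012,2012-04-30,2012-05-16,,2012-09-18,4980,125
SYNCAL03,2013,2013-04-30,2013-05-19,2013-07-18,2013-09-22,5210,126
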