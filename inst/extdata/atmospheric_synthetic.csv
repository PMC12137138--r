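"year","f14c"
1950,0.98881
1951,0.99548
1952,1.00528
1953,1.01959
1954,1.04027
1955,1.0697
1956,1.11072
1957,1.16625
1958,1.23854
1959,1.32798
1960,1.43191
1961,1.54427
1962,1.65663
1963,1.76057
1964,1.85
1965,1.7985
1966,1.75012
1967,1.70467
1968,1.66198
1969,1.62187
1970,1.5842
1971,1.5488
1972,1.51555
1973,1.48432
1974,1.45497
1975,1.42741
1976,1.40151
1977,1.37719
1978,1.35433
1979,1.33286
1980,1.3127
1981,1.29375
1982,1.27595
1983,1.25924
1984,1.24353
1985,1.22877
1986,1.21491
1987,1.20189
1988,1.18966
1989,1.17817
1990,1.16737
1991,1.15723
1992,1.14771
1993,1.13876
1994,1.13035
1995,1.12245
1996,1.11503
1997,1.10807
1998,1.10152
1999,1.09537
2000,1.08959
2001,1.08416
2002,1.07906
2003,1.07427
2004,1.06977
2005,1.06554
2006,1.06157
2007,1.05784
2008,1.05434
2009,1.05105
2010,1.04795
2011,1.04505
2012,1.04232
2013,1.03976
2014,1.03735
2015,1.03508
2016,1.03296
2017,1.03096
2018,1.02909
2019,1.02732
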