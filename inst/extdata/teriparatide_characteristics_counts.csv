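section,category,count,printed_percent
year,2004,6279,5.86
year,2005,4655,4.35
year,2006,2134,1.99
year,2007,2118,1.98
year,2008,2051,1.91
year,2009,2926,2.73
year,2010,3635,3.39
year,2011,5070,4.73
year,2012,6138,5.73
year,2013,5503,5.14
year,2014,1433,1.34
year,2015,44728,41.75
year,2016,2075,1.94
year,2017,3921,3.66
year,2018,4734,4.42
year,2019,3840,3.58
year,2020,1871,1.75
year,2021,1601,1.49
year,2022,1357,1.27
year,2023,1054,0.98
gender,Female,95959,89.58
gender,Male,9918,9.26
gender,Unknown,1246,1.16
age,<18,65,0.06
age,18-45,1015,0.95
age,45-65,15294,14.28
age,65-75,17931,16.74
age,>=75,26144,24.41
age,Unknown,46674,43.57
onset,<7,8496,11.21
onset,7-28,3275,4.32
onset,28-60,2904,3.83
onset,>=60,13973,18.44
onset,Unknown,47116,62.19
reporter,Consumer,74785,69.81
reporter,Physician,11638,10.86
reporter,Unknown,9285,8.67
reporter,Other health-professional,6787,6.34
reporter,Pharmacist,4542,4.24
reporter,Registered Nurse,82,0.08
reporter,Lawyer,4,0.00
country,United States,63138,58.94
country,Other,35009,32.68
country,Spain,2584,2.41
country,Japan,2296,2.14
country,Germany,789,0.74
route,Other,77404,72.26
route,Subcutaneous,29550,27.59
route,Oral,102,0.10
route,Intramuscular,53,0.05
route,Intravenous,14,0.01
outcomes,Hospitalization,24496,47.87
outcomes,Other serious,19899,38.88
outcomes,Death,5460,10.67
outcomes,Disability,641,1.25
outcomes,Life threatening,602,1.18
outcomes,Required intervention to Prevent Permanent Impairment/Damage,72,0.14
outcomes,Congenital anomaly,5,0.01
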