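#trial	mapped_reads	mapped_sites	raw_snps	unintended_snps	caller_passed	filtered
Trial.1	9734787	80552288	8872433	8358426	350694	231972
Trial.2	9735558	80558479	8878304	8365007	350670	232496
Trial.3	9733473	80568898	8880681	8366553	350136	231912
Trial.4	9733159	80570416	8879502	8365311	350442	231539
Trial.5	9733939	80545810	8853408	8339822	350332	232008
Trial.6	9733507	80542007	8838870	8326074	350917	232649
Trial.7	9734222	80555307	8859741	8346628	350390	232128
Trial.8	9735046	80562701	8874369	8361655	350807	232063
Trial.9	9733971	80555609	8852720	8339866	350059	232336
Trial.10	9734717	80542143	8863065	8350655	350809	232347
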