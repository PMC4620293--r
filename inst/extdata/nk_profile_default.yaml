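# Default cohort profile sheet: per-subset marker expression summaries
# (percent positive, MFI on the 0-10,000 linear scale, CV %) for blood
# NK-cell subsets, with between-subject SD and min-max ranges.
# protocol1 cells describe the conventional two-subset analysis
# (columns: low = conventional CD56+low gate, which pools the true
# CD56+low and CD56+int populations; high = CD56+high); MFI/CV there are
# over all subset events. threeway cells describe the three-way subsets;
# mfi_mode says whether the printed MFI/CV refer to all subset events
# ("all") or to positively stained cells only ("positives").

cohort:
  n_subjects: 15
  n_events_per_tube: 200000

background: {mfi: 3.0, cv: 1.0}

# percent of all acquired (lymphocyte) events; NK is split by shares
population_frequencies: {T: 73.0, B: 12.0, NK: 13.0, other: 2.0}

# percent of CD56+ NK events
shares:
  NK_low:  {mean: 90.3, sd: 3.9, min: 83.4, max: 98.0}
  NK_int:  {mean: 6.1,  sd: 4.0, min: 1.2,  max: 14.6}
  NK_high: {mean: 3.7,  sd: 2.3, min: 0.9,  max: 8.5}

# channel means (a.u.); event_sd is the within-subject event-level SD
scatter:
  NK_low:  {fsc: 299, ssc: 151}
  NK_int:  {fsc: 303, ssc: 156}
  NK_high: {fsc: 311, ssc: 159}
  T:       {fsc: 295, ssc: 145}
  B:       {fsc: 290, ssc: 140}
  other:   {fsc: 280, ssc: 170}
  event_sd: {fsc: 25, ssc: 15}

# subject-level correlation between percent CXCR3+ and percent CCR5+
# among true CD56+low NK-cells
correlated_pairs:
  - {a: p1.CXCR3.lowtrue.pct, b: p1.CCR5.lowtrue.pct, r: 0.656}

protocol1:
  CXCR1:
    low:
      pct: {mean: 93.0, sd: 4.5, min: 85.3, max: 99.6}
      mfi: {mean: 100.1, sd: 19.4, min: 79.3, max: 140.9}
      cv: 67.1
    high:
      pct: {mean: 4.0, sd: 3.6, min: 0.0, max: 12.1}
      mfi: {mean: 7.0, sd: 3.1, min: 2.0, max: 14.5}
      cv: 156.8
  CXCR2:
    low:
      pct: {mean: 91.9, sd: 3.4, min: 86.1, max: 97.0}
      mfi: {mean: 165.7, sd: 68.6, min: 66.9, max: 264.1}
      cv: 64.1
    high:
      pct: {mean: 2.0, sd: 1.4, min: 0.0, max: 4.7}
      mfi: {mean: 3.6, sd: 1.5, min: 2.2, max: 6.8}
      cv: 218.1
  CXCR3:
    low:
      pct: {mean: 15.6, sd: 11.1, min: 4.8, max: 40.1}
      mfi: {mean: 15.5, sd: 10.7, min: 6.5, max: 41.6}
      cv: 209.8
    high:
      pct: {mean: 97.0, sd: 2.5, min: 92.5, max: 99.6}
      mfi: {mean: 94.5, sd: 55.1, min: 48.7, max: 231.1}
      cv: 62.7
  CXCR4:
    low:
      pct: {mean: 21.8, sd: 8.7, min: 8.4, max: 43.5}
      mfi: {mean: 11.8, sd: 3.9, min: 5.3, max: 20.9}
      cv: 308.5
    high:
      pct: {mean: 11.4, sd: 4.6, min: 5.5, max: 21.4}
      mfi: {mean: 7.8, sd: 3.1, min: 3.6, max: 14.0}
      cv: 318.6
  CCR4:
    low:
      pct: {mean: 0.8, sd: 0.4, min: 0.2, max: 1.5}
      mfi: {mean: 2.2, sd: 0.6, min: 1.3, max: 3.0}
      cv: 393.3
    high:
      pct: {mean: 3.3, sd: 2.9, min: 0.3, max: 9.7}
      mfi: {mean: 3.1, sd: 1.1, min: 1.5, max: 4.4}
      cv: 118.7
  CCR5:
    low:
      pct: {mean: 13.3, sd: 8.8, min: 2.8, max: 33.2}
      mfi: {mean: 11.1, sd: 6.0, min: 3.5, max: 20.6}
      cv: 353.5
    high:
      pct: {mean: 50.0, sd: 15.3, min: 24.8, max: 78.5}
      mfi: {mean: 27.8, sd: 18.6, min: 7.7, max: 79.9}
      cv: 133.9
  CCR6:
    low:
      pct: {mean: 0.6, sd: 0.4, min: 0.1, max: 1.3}
      mfi: {mean: 2.3, sd: 0.7, min: 1.5, max: 3.9}
      cv: 214.7
    high:
      pct: {mean: 0.9, sd: 1.2, min: 0.0, max: 3.0}
      mfi: {mean: 2.1, sd: 0.8, min: 1.4, max: 4.0}
      cv: 106.7

threeway:
  CD56:
    mfi_mode: all
    NK_low:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 466, sd: 108, min: 303, max: 623}
      cv: 57
    NK_int:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 615, sd: 149, min: 416, max: 999}
      cv: 72
    NK_high:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 2926, sd: 578, min: 2161, max: 3993}
      cv: 37
  CD16:
    mfi_mode: all
    NK_low:
      pct: {mean: 99.9, sd: 0.1, min: 99.9, max: 100.0}
      mfi: {mean: 226, sd: 107, min: 55, max: 372}
      cv: 45
    NK_int:
      pct: {mean: 64.6, sd: 23.6, min: 26.8, max: 96.2}
      mfi: {mean: 84, sd: 55, min: 25, max: 201}
      cv: 79
    NK_high:
      pct: {mean: 28.7, sd: 9.9, min: 9.9, max: 43.5}
      mfi: {mean: 47, sd: 18, min: 21, max: 47}
      cv: 81
  CD57:
    mfi_mode: positives
    NK_low:
      pct: {mean: 66.3, sd: 15.6, min: 36.7, max: 87.4}
      mfi: {mean: 700, sd: 436, min: 217, max: 1557}
      cv: 114
    NK_int:
      pct: {mean: 15.3, sd: 13.7, min: 1.7, max: 42.7}
      mfi: {mean: 355, sd: 166, min: 150, max: 703}
      cv: 130
    NK_high:
      pct: {mean: 1.3, sd: 1.4, min: 0.0, max: 4.3}
      mfi: {mean: 165, sd: 219, min: 9, max: 574}
      cv: 85
  CD62L:
    mfi_mode: positives
    NK_low:
      pct: {mean: 35.4, sd: 20.4, min: 9.6, max: 73.5}
      mfi: {mean: 49, sd: 9, min: 38, max: 65}
      cv: 83
    NK_int:
      pct: {mean: 77.3, sd: 19.0, min: 41.9, max: 95.7}
      mfi: {mean: 119, sd: 21, min: 77, max: 147}
      cv: 56
    NK_high:
      pct: {mean: 97.3, sd: 2.4, min: 92.8, max: 100.0}
      mfi: {mean: 139, sd: 30, min: 91, max: 172}
      cv: 47
  CD94:
    mfi_mode: positives
    NK_low:
      pct: {mean: 47.8, sd: 13.7, min: 34.1, max: 74.1}
      mfi: {mean: 71, sd: 18, min: 50, max: 106}
      cv: 56
    NK_int:
      pct: {mean: 91.4, sd: 6.0, min: 79.2, max: 98.4}
      mfi: {mean: 129, sd: 34, min: 77, max: 211}
      cv: 56
    NK_high:
      pct: {mean: 98.3, sd: 1.5, min: 94.5, max: 100.0}
      mfi: {mean: 228, sd: 34, min: 175, max: 286}
      cv: 47
  CD122:
    mfi_mode: positives
    NK_low:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 46, sd: 11, min: 31, max: 63}
      cv: 50
    NK_int:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 77, sd: 20, min: 49, max: 107}
      cv: 56
    NK_high:
      pct: {mean: 100.0, sd: 0.0, min: 100.0, max: 100.0}
      mfi: {mean: 117, sd: 32, min: 79, max: 182}
      cv: 46
  CD158a:
    mfi_mode: positives
    NK_low:
      pct: {mean: 38.9, sd: 30.0, min: 7.9, max: 92.9}
      mfi: {mean: 30, sd: 8, min: 18, max: 42}
      cv: 61
    NK_int:
      pct: {mean: 9.9, sd: 9.0, min: 0.7, max: 30.0}
      mfi: {mean: 35, sd: 11, min: 22, max: 57}
      cv: 63
    NK_high:
      pct: {mean: 4.1, sd: 4.9, min: 0.1, max: 19.3}
      mfi: {mean: 41, sd: 13, min: 20, max: 68}
      cv: 69
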