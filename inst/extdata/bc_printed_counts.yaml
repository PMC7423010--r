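# Published counts of a nine-year IRT-DNA-IRT cystic fibrosis newborn
# screening programme (British Columbia and Yukon, 2010-2018). Keys ending
# in _printed are the derived values as printed in the programme's public
# performance summary; all other keys are raw counts. reproducePrintedCounts()
# recomputes every derived value from the raw counts and compares.

# cohort and case totals
n_screened: 401977
cf_total: 76
cfspid_total: 28

# true-positive accounting by detection channel
true_positive_cf: 70
true_positive_all: 95
meconium_ileus_cases: 3
two_mutation_referrals: 77
two_mutation_cf: 57
one_mut_high_irt2_cf: 10
one_mut_high_irt2_all: 13
optional_sweat_cf: 0
optional_sweat_cfspid: 2
failsafe_detected: 0

# day-21 repeat-IRT tier
carriers_normal_irt2: 880
optional_sweats_done: 115
failsafe_normal_irt2: 271

# false-negative accounting by channel
false_negative_cf: 6
false_negative_all: 9
fn_normal_irt1_cf: 4
fn_normal_irt1_all: 5
fn_no_mutation: 2
fn_no_sweat_cfspid: 1
fn_high_irt2_normal_sweat_cfspid: 1

# printed derived values to reproduce
ppv_two_mut_cf_printed: 74
ppv_two_mut_all_printed: 100
ppv_one_mut_cf_printed: 29
ppv_one_mut_all_printed: 38
uptake_pct_printed: 13
sweat_tests_avoided_printed: 1036
npv_day21_cf_printed: 100
npv_day21_cfspid_printed: 99.7
incidence_cf_printed: 5289
incidence_all_printed: 3865
cases_all_printed: 104
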