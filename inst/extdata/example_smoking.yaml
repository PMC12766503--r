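# Smoking-cessation screening example: flag duplicates on identical
# first AND last name, OR identical email, OR identical phone, within a
# six-month (183-day) window; enroll N = 143 with minimums of 23 per
# cigarettes-per-day bin and 36 recent quitters.
timezone: UTC
seed: 20240101
dedup_mode: review

schema:
  - {name: first_name, role: identifier, normalizer: text}
  - {name: last_name,  role: identifier, normalizer: text}
  - {name: email,      role: identifier, normalizer: email}
  - {name: phone,      role: identifier, normalizer: phone}
  - {name: category,   role: eligibility, normalizer: exact}

criteria:
  window_days: 183
  rules:
    - {label: name,  fields: [first_name, last_name]}
    - {label: email, fields: [email]}
    - {label: phone, fields: [phone]}

quota:
  total_n: 143
  block_size: ~
  check_time: enrollment
  rules:
    - {label: cpd-1-5-min,   when: {category: cpd_1_5},     bound: minimum, amount: 23, kind: count}
    - {label: cpd-6-10-min,  when: {category: cpd_6_10},    bound: minimum, amount: 23, kind: count}
    - {label: cpd-11-15-min, when: {category: cpd_11_15},   bound: minimum, amount: 23, kind: count}
    - {label: cpd-16up-min,  when: {category: cpd_16_plus}, bound: minimum, amount: 23, kind: count}
    - {label: quit-30-min,   when: {category: quit_30},     bound: minimum, amount: 36, kind: count}
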