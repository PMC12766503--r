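# Minimal example: six-participant sample, no blocks, at most two male
# participants; duplicates flagged on name or email within one year.
timezone: UTC
seed: 7
dedup_mode: auto

schema:
  - {name: first_name, role: identifier, normalizer: text}
  - {name: last_name,  role: identifier, normalizer: text}
  - {name: email,      role: identifier, normalizer: email}
  - {name: sex,        role: demographic, normalizer: exact}

criteria:
  window_days: 365
  rules:
    - {label: name,  fields: [first_name, last_name]}
    - {label: email, fields: [email]}

quota:
  total_n: 6
  check_time: screening
  rules:
    - {label: male-max, when: {sex: male}, bound: maximum, amount: 2, kind: count}
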