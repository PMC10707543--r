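# Index-hierarchy configuration schema, by example.
# Each entry: id, level (primary|secondary|tertiary), parent (omit for
# primary), direction (high_optimal default; low_optimal = smaller is
# better), name, units. The optional weights mapping is keyed by sex;
# within every sibling set weights must sum to 1 (within 0.005).
indexes:
  - {id: body_form, name: Body form, level: primary}
  - {id: physiological_function, name: Physiological function, level: primary}
  - {id: physical_quality, name: Physical quality, level: primary}
  - {id: achilles_tendon_length, name: Achilles tendon length, level: tertiary,
     parent: body_form, units: cm}
  - {id: pelvis_width, name: Pelvis width, level: tertiary,
     parent: body_form, units: cm}
  - {id: waist_circumference, name: Waist circumference, level: tertiary,
     parent: body_form, units: cm}
  - {id: quetelet_index, name: Quetelet index, level: tertiary,
     parent: body_form, units: g/cm}
  - {id: rel_max_anaerobic_power, name: Relative maximum anaerobic power,
     level: tertiary, parent: physiological_function, units: W/kg}
  - {id: rel_max_oxygen_uptake, name: Relative maximum oxygen uptake,
     level: tertiary, parent: physiological_function, units: ml/kg/min}
  - {id: hemoglobin, name: Hemoglobin, level: tertiary,
     parent: physiological_function, units: g/L}
  - {id: power_clean, name: Power clean, level: tertiary,
     parent: physical_quality, units: kg}
  - {id: squat_balance_pad,
     name: Squat on the balance pad with the barbell raising,
     level: tertiary, parent: physical_quality, direction: low_optimal,
     units: s}
  - {id: sprint_30m, name: 30-meter sprint, level: tertiary,
     parent: physical_quality, direction: low_optimal, units: s}
  - {id: run_12min, name: 12-minute run, level: tertiary,
     parent: physical_quality, units: m}
weights:
  male:
    body_form: 0.25
    physiological_function: 0.33
    physical_quality: 0.42
    achilles_tendon_length: 0.24
    pelvis_width: 0.23
    waist_circumference: 0.31
    quetelet_index: 0.22
    rel_max_anaerobic_power: 0.35
    rel_max_oxygen_uptake: 0.31
    hemoglobin: 0.34
    power_clean: 0.30
    squat_balance_pad: 0.29
    sprint_30m: 0.20
    run_12min: 0.21
  female:
    body_form: 0.27
    physiological_function: 0.32
    physical_quality: 0.41
    achilles_tendon_length: 0.23
    pelvis_width: 0.22
    waist_circumference: 0.30
    quetelet_index: 0.25
    rel_max_anaerobic_power: 0.36
    rel_max_oxygen_uptake: 0.29
    hemoglobin: 0.35
    power_clean: 0.27
    squat_balance_pad: 0.28
    sprint_30m: 0.20
    run_12min: 0.25
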