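# Default clinical-profile registry: six concussion clinical profiles
# (AMSSM subtype framework) operationalized as subsets of the 22 SCAT5
# symptom-checklist items. A profile is assigned when at least
# threshold_rule(subset size) of its symptoms are endorsed at or above
# endorsement_min_severity. Profiles overlap and are not mutually
# exclusive. Edit or replace this file to use an alternative mapping.
endorsement_min_severity: 1
threshold_rule: half_floor
profiles:
  vestibular:
    - dizziness
    - balance_problems
    - nausea_or_vomiting
    - blurred_vision
    - feeling_like_in_a_fog
    - dont_feel_right
  cognitive:
    - feeling_slowed_down
    - feeling_like_in_a_fog
    - dont_feel_right
    - difficulty_concentrating
    - difficulty_remembering
    - confusion
    - fatigue_or_low_energy
  fatigue:
    - fatigue_or_low_energy
    - drowsiness
    - trouble_falling_asleep
    - feeling_slowed_down
    - dont_feel_right
  anxiety_mood:
    - more_emotional
    - irritability
    - sadness
    - nervous_or_anxious
    - trouble_falling_asleep
    - difficulty_concentrating
    - dont_feel_right
  headache_migraine:
    - headache
    - pressure_in_head
    - neck_pain
    - nausea_or_vomiting
    - sensitivity_to_light
    - sensitivity_to_noise
  ocular:
    - headache
    - pressure_in_head
    - blurred_vision
    - sensitivity_to_light
    - difficulty_concentrating
    - fatigue_or_low_energy
    - dizziness
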