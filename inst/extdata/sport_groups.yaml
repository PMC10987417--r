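# Sport -> sport-group mapping used to collapse the 27 collegiate sports
# represented in the cohort into 11 groups large enough for mixed-model
# cluster-size requirements. This default grouping is by similarity of
# sport; edit to match a particular conference's roster. Sports absent
# from the table fall into the `default_group` with a warning.
default_group: other
groups:
  football: [football]
  soccer: [soccer]
  basketball: [basketball]
  volleyball: [volleyball, beach_volleyball]
  water_sports: [swimming, diving, water_polo]
  track_running: [track_and_field, cross_country, rowing]
  gymnastics_dance: [gymnastics, cheerleading, dance]
  combat_contact: [wrestling, rugby, martial_arts]
  baseball_softball: [baseball, softball]
  stick_sports: [lacrosse, field_hockey, ice_hockey]
  other: [tennis, golf, fencing, skiing, equestrian]
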