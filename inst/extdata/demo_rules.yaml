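- rule_id: bat_bed
  sensor_id: bed
  kind: low_battery
  threshold: 20.0
- rule_id: bat_chair
  sensor_id: chair
  kind: low_battery
  threshold: 20.0
- rule_id: bat_toilet
  sensor_id: toilet
  kind: low_battery
  threshold: 20.0
- rule_id: bat_fridge
  sensor_id: fridge
  kind: low_battery
  threshold: 20.0
- rule_id: bat_door
  sensor_id: door
  kind: low_battery
  threshold: 20.0
- rule_id: bat_pir
  sensor_id: pir
  kind: low_battery
  threshold: 20.0
- rule_id: bat_tv
  sensor_id: tv
  kind: low_battery
  threshold: 20.0
- rule_id: door_open
  sensor_id: door
  kind: prolonged_state
  threshold: 480.0
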