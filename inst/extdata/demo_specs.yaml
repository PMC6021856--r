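- sensor_id: bed
  kind: binary_state
  keepalive_interval: 60.0
- sensor_id: chair
  kind: binary_state
  keepalive_interval: 60.0
- sensor_id: toilet
  kind: impulsive
  keepalive_interval: 60.0
- sensor_id: fridge
  kind: impulsive
  keepalive_interval: 60.0
- sensor_id: door
  kind: impulsive
  keepalive_interval: 60.0
- sensor_id: pir
  kind: impulsive
  keepalive_interval: 60.0
- sensor_id: tv
  kind: real_valued
  binarize_threshold: 20.0
  keepalive_interval: 60.0
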