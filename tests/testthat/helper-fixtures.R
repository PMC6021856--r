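# shared fixture builders; everything is generated in code

utc <- function(x) as.POSIXct(x, tz = "UTC")

event_row <- function(obj_id, variable_id, ts, int_value = NA_integer_,
                      float_value = NA_real_, gtw_id = "g1") {
  data.frame(gtw_id = gtw_id, obj_id = obj_id, variable_id = variable_id,
             ts = utc(ts), int_value = as.integer(int_value),
             float_value = as.numeric(float_value),
             string_value = NA_character_, flags = NA_integer_,
             stringsAsFactors = FALSE)
}

# an ON/OFF pair for a binary sensor
session_events <- function(obj_id, on, off) {
  rbind(event_row(obj_id, "status", on, 1L),
        event_row(obj_id, "status", off, 0L))
}

bed_spec <- function() sensor_spec("bed", "binary_state")

# three planted habit modes over bed + chair, shared across MHC tests
planted_modes <- function() {
  list(
    list(list(sensor = "bed", start = 1, duration = 14),
         list(sensor = "bed", start = 44, duration = 5),
         list(sensor = "chair", start = 20, duration = 6),
         list(sensor = "chair", start = 30, duration = 8)),
    list(list(sensor = "bed", start = 1, duration = 12),
         list(sensor = "bed", start = 27, duration = 4),
         list(sensor = "bed", start = 45, duration = 4),
         list(sensor = "chair", start = 17, duration = 5)),
    list(list(sensor = "bed", start = 1, duration = 16),
         list(sensor = "chair", start = 25, duration = 12),
         list(sensor = "chair", start = 40, duration = 4))
  )
}

# brute-force Holm step-down straight from its definition, kept independent
# of the package implementation
holm_brute_force <- function(p, alpha = 0.05) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p of test i: max over all j with p_j <= p_i of (m - rank + 1) p_j
    cand <- numeric(0)
    o <- order(p)
    for (r in seq_len(m)) {
      j <- o[r]
      if (p[j] <= p[i] || j == i) cand <- c(cand, (m - r + 1) * p[j])
      if (j == i) break
    }
    adj[i] <- min(1, max(cand))
  }
  list(p_adj = adj, reject = adj <= alpha)
}

# independent scalar evaluation of the GRU recurrence, plain arithmetic
gru_scalar_oracle <- function(wz, uz, bz, wr, ur, br, wh, uh, bh, x, h) {
  sg <- function(a) 1 / (1 + exp(-a))
  z <- sg(wz * x + uz * h + bz)
  r <- sg(wr * x + ur * h + br)
  cand <- tanh(wh * x + uh * (r * h) + bh)
  (1 - z) * h + z * cand
}

# brute-force valid cross-correlation + ReLU + max-pool for one input map
conv_brute_force <- function(x, kernel, bias, pool) {
  T_out <- length(x) - length(kernel) + 1
  y <- numeric(T_out)
  for (t in seq_len(T_out)) {
    y[t] <- max(0, bias + sum(kernel * x[t:(t + length(kernel) - 1)]))
  }
  if (pool <= 1) return(y)
  ng <- T_out %/% pool
  vapply(seq_len(ng), function(g) max(y[((g - 1) * pool + 1):(g * pool)]),
         numeric(1))
}

# a 12-hour two-sensor log with regular keep-alives, good batteries and
# short sessions: nothing in it should trip a rule
healthy_log <- function() {
  specs <- rbind(sensor_spec("door", "binary_state"),
                 sensor_spec("bed", "binary_state"))
  t0 <- utc("2024-03-01 00:00:00")
  ka <- do.call(rbind, lapply(seq(0, 11.5 * 3600, by = 3600), function(s) {
    rbind(event_row("door", "keepalive", t0 + s),
          event_row("bed", "keepalive", t0 + s))
  }))
  bat <- rbind(event_row("door", "battery", t0, int_value = 98L),
               event_row("bed", "battery", t0 + 6 * 3600, int_value = 97L))
  st <- rbind(session_events("door", t0 + 3600, t0 + 3660),
              session_events("bed", t0 + 2 * 3600, t0 + 6 * 3600))
  list(log = event_log(rbind(ka, bat, st), specs), specs = specs,
       now = t0 + 12 * 3600)
}

default_rules <- function() {
  rbind(rule_spec("r_bat_door", "door", "low_battery", 20),
        rule_spec("r_bat_bed", "bed", "low_battery", 20),
        rule_spec("r_ka_door", "door", "keepalive_gap", 2),
        rule_spec("r_ka_bed", "bed", "keepalive_gap", 2),
        rule_spec("r_open_door", "door", "prolonged_state", 480),
        rule_spec("r_bed_long", "bed", "prolonged_state", 720))
}
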