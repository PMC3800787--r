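# Shared expensive fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# calibrated broadband-transient call (the lag-identification probe: its
# envelope has sharp landmarks, unlike the quasi-periodic TSV envelope)
bt_stim_60db <- function() fixture("bt_stim_60db", function() {
  calibrate_level(synth_call("BT", duration_ms = 500, seed = 11), 60)
})

# its full-model envelope at an 8-kHz channel
bt_env_8k <- function() fixture("bt_env_8k", function() {
  drnl_output(bt_stim_60db(), 8000)
})
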