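# shared fixtures: the four mortality parameterizations used throughout
all_presets <- function(y_min = 0L, y_max = 50L)
  sapply(c("combined", "state_independent", "decreasing", "increasing"),
         mortality_preset, y_min = y_min, y_max = y_max,
         simplify = FALSE)

# small grid for exhaustive / brute-force checks
small_config <- function(...)
  dsv_config(y_min = 0L, y_max = 10L, T_steps = 5L,
             mortality = mortality_model("constant", intercept = 0.1,
                                         y_min = 0L, y_max = 10L),
             ...)
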