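# Shared fixtures: fast synthetic records/episodes and tiny model configs.

options(rhythmnet.quiet = TRUE)

quiet_record <- function(class = "N", fs = 250, duration = 10, seed = 1,
                         mean_hr = NULL, rr_cv = NULL, noise = NULL, ...) {
  rp <- rhythm_params(class, mean_hr = mean_hr, rr_cv = rr_cv, ...)
  generate_record(synth_config(fs = fs, duration = duration, rhythm = rp,
                               noise = noise %||% noise_params(0, 0.3, 0, 0),
                               seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny network on short inputs so model/training tests run in seconds
tiny_config <- function(n_classes = 2L, input_length = 64L)
  small_model_config(n_classes, input_length = input_length,
                     filters = c(4L, NA), dense = 8L)

# episode store of short constant-vs-oscillating "episodes": a separable
# toy problem for protocol structure tests
toy_episode_table <- function(n_per_class = 20, input_length = 64L,
                              classes = c("N", "AF"), seed = 1) {
  set.seed(seed)
  eps <- list()
  i <- 0L
  for (cl in classes) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    base <- switch(cl,
                   N = sin(2 * pi * (1:input_length) / 16),
                   AF = sin(2 * pi * (1:input_length) / 5),
                   NON_AF = rep_len(c(1, -1), input_length))
    eps[[i]] <- ecg_episode(base + rnorm(input_length, 0, 0.1),
                            label = cl, parent_record = sprintf("r%d", i),
                            fs = 64, subject_id = sprintf("S%02d", i),
                            length = input_length)
  }
  episodes_to_table(eps)
}
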