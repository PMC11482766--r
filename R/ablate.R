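#' Train and compare gate-ablated architectures
#'
#' Trains the full gated architecture and its ablations (reset gate fixed
#' open, update gate fixed open, no gates) on the single-trial-then-
#' two-trial schedule with matched seeds and parameter-matched hidden
#' sizes, and evaluates each on the noise-free two-trial grid. The update
#' gate is what lets a network hold state across the delay and overwrite
#' it at the cue, so its ablation is expected to hurt two-trial
#' performance most.
#'
#' @param spec a `curriculum_spec` (the `2-trial` schedule is used
#'   regardless of its `switch_training`).
#' @param modes architectures to train.
#' @param net_seed shared seed.
#' @return data.frame with one row per mode: hidden size, parameter count,
#'   overall test loss, trial-2 switch and repeat loss.
#' @export
ablate_gates <- function(spec, modes = c("full", "open_reset", "open_update",
                                         "no_gates"),
                         net_seed = spec$seed) {
  spec$switch_training <- "2-trial"
  rows <- lapply(modes, function(m) {
    net <- train_curriculum(spec, mode = m, net_seed = net_seed)
    ev <- evaluate_network(net$params, spec, 2)
    data.frame(mode = m, hidden = net$params$hidden_size,
               n_params = gru_n_params(net$params),
               loss = ev$loss, switch_loss = ev$switch_loss,
               repeat_loss = ev$repeat_loss)
  })
  do.call(rbind, rows)
}
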