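# Condition helpers. Pipeline stages and the CLI map these classes onto
# distinct exit codes (config = 2, format = 3, consistency = 4).

ps_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ps_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ps_input_error       <- function(msg, ...) ps_abort("ps_input_error", msg, ...)
ps_format_error      <- function(msg, ...) ps_abort("ps_format_error", msg, ...)
ps_consistency_error <- function(msg, ...) ps_abort("ps_consistency_error", msg, ...)
ps_config_error      <- function(msg, ...) ps_abort("ps_config_error", msg, ...)
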