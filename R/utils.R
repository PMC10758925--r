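# Resolve a tidy-eval column argument: bare name, or an expression
# evaluating to a single string (so programmatic loops can pass labels).
resolve_col <- function(quo) {
  expr <- rlang::quo_get_expr(quo)
  if (rlang::is_symbol(expr)) return(rlang::as_name(expr))
  val <- rlang::eval_tidy(quo)
  if (!is.character(val) || length(val) != 1) {
    abort("channel must be a bare column name or a single string",
          class = "ccmdi_domain_error")
  }
  val
}
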