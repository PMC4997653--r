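# fixtures built in code; nothing is stored on disk

# mutual negation: a -> b, b -> a, each node updates to NOT(its input)
mutual_negation_bn <- function() {
  net <- directed_network(cbind(c("a", "b"), c("b", "a")))
  boolean_network(net, list(
    a = list(inputs = "b", outputs = c(1L, 0L)),
    b = list(inputs = "a", outputs = c(1L, 0L))))
}

# source -> target with the identity function: the target copies the source
identity_chain_bn <- function() {
  net <- directed_network(cbind("s", "t"))
  boolean_network(net, list(t = list(inputs = "s", outputs = c(0L, 1L))))
}

write_tmp_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}
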