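# hand-built dictionary fixtures for unit tests

# coordinate subset of the j-th dictionary column
dict_term_subset <- function(dict, j) {
  sizes <- vapply(dict$groups, function(g) nrow(g$knots), integer(1))
  gi <- findInterval(j - 1L, cumsum(c(0L, sizes)), rightmost.closed = TRUE)
  dict$groups[[gi]]$s
}

dict_fixture <- function(s_list, knots, d, order = 0L) {
  groups <- Map(function(s, u) {
    u <- as.matrix(u)
    dimnames(u) <- NULL
    storage.mode(u) <- "double"
    list(s = as.integer(s), knots = u)
  }, s_list, knots)
  structure(
    list(order = as.integer(order), d = as.integer(d), groups = groups,
         p = sum(vapply(groups, function(g) nrow(g$knots), numeric(1))),
         dedup = NULL),
    class = "hal_dictionary")
}
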