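# Brute-force metric oracles used against the vectorised implementations.

# O(n^2) enumeration of positive-negative score pairs, ties counting half
bf_auroc <- function(labels, scores) {
  p <- scores[labels == 1L]; n <- scores[labels == 0L]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# threshold enumeration: walk every unique score as a calling threshold and
# accumulate precision times the recall increment
bf_auprc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    called <- scores >= t
    prec <- sum(labels[called] == 1L) / sum(called)
    rec <- sum(labels[called] == 1L) / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
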