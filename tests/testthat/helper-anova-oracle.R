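# Brute-force sums-of-squares oracle for the 2 x 2 x 2 mixed design
# (one between factor, two within factors, balanced).
ss_oracle_222 <- function(d) {
  gm <- mean(d$dv)
  cm <- function(...) tapply(d$dv, lapply(c(...), function(v) d[[v]]), mean)
  n_s <- length(unique(d$subject))
  ss_sub <- sum((cm("subject") - gm)^2) * 4
  ss_g <- sum((cm("group") - gm)^2) * (n_s / 2) * 4
  m1 <- cm("w1"); ss_w1 <- sum((m1 - gm)^2) * n_s * 2
  m2 <- cm("w2"); ss_w2 <- sum((m2 - gm)^2) * n_s * 2
  ss_gw1 <- sum((cm("group", "w1") - gm)^2) * (n_s / 2) * 2 - ss_g - ss_w1
  ss_gw2 <- sum((cm("group", "w2") - gm)^2) * (n_s / 2) * 2 - ss_g - ss_w2
  ss_w12 <- sum((cm("w1", "w2") - gm)^2) * n_s - ss_w1 - ss_w2
  ss_sw1 <- sum((cm("subject", "w1") - gm)^2) * 2 - ss_sub - ss_w1 - ss_gw1
  ss_sw2 <- sum((cm("subject", "w2") - gm)^2) * 2 - ss_sub - ss_w2 - ss_gw2
  ss_gw12 <- sum((cm("group", "w1", "w2") - gm)^2) * (n_s / 2) -
    ss_g - ss_w1 - ss_w2 - ss_gw1 - ss_gw2 - ss_w12
  ss_tot <- sum((d$dv - gm)^2)
  list(group = ss_g, sub_err = ss_sub - ss_g,
       w1 = ss_w1, `group:w1` = ss_gw1, sw1_err = ss_sw1,
       w2 = ss_w2, `group:w2` = ss_gw2, sw2_err = ss_sw2,
       `w1:w2` = ss_w12, `group:w1:w2` = ss_gw12,
       resid = ss_tot - ss_sub - ss_w1 - ss_w2 - ss_gw1 - ss_gw2 -
         ss_w12 - ss_gw12 - ss_sw1 - ss_sw2,
       total = ss_tot)
}

toy_222 <- function(seed = 9) {
  set.seed(seed)
  d <- expand.grid(subject = paste0("s", 1:8), w1 = c("a", "b"),
                   w2 = c("x", "y"), stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% paste0("s", 1:4), "g1", "g2")
  d$dv <- as.numeric(sample(1:20, nrow(d), replace = TRUE))
  d
}

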