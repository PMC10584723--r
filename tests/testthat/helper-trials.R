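# Build a small trial-record table with sensible defaults.
make_records <- function(face1, face2, response, rt = 5,
                         isi = 1, delay = 1, postcue = NA_integer_,
                         participant = "p1", session = 1L) {
  n <- max(lengths(list(face1, face2, response)))
  data.frame(participant = participant, session = session,
             trial = seq_len(n),
             isi_s = rep_len(isi, n), delay_s = rep_len(delay, n),
             face1 = rep_len(face1, n), face2 = rep_len(face2, n),
             postcue = rep_len(postcue, n),
             response = rep_len(response, n),
             rt_s = rep_len(rt, n),
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the signed shortest circular path:
# walk clockwise and counterclockwise step counts separately and keep the
# shorter, breaking the antipodal tie (even wheels) clockwise.
oracle_signed_distance <- function(a, b, n) {
  cw <- (b - a) %% n
  ccw <- (a - b) %% n
  if (cw <= ccw) cw else -ccw
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)
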