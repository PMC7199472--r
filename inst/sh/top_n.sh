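#!/bin/sh
# Keep the N highest-scoring molecule records of an SDF-dialect file.
# Records are "$$$$"-terminated; each carries a "> <score>" data tag whose
# value is on the following line. Keeping the best N of any subset is
# associative and commutative, so this command is safe at every level of a
# tree reduce.
#
# usage: top_n.sh IN.sdf OUT.sdf [N]
set -e
N=${3:-30}
awk -v n="$N" '
  /^\$\$\$\$$/ {
    cnt += 1
    recs[cnt] = rec
    sc[cnt] = score + 0
    rec = ""
    seen = 0
    next
  }
  {
    if (seen == 0) { rec = $0; seen = 1 } else { rec = rec "\n" $0 }
    if (grab == 1) { score = $0; grab = 0 }
    if ($0 ~ /^> *<score>/) grab = 1
  }
  END {
    if (n > cnt) n = cnt
    for (i = 1; i <= n; i++) {
      best = 0
      for (j = 1; j <= cnt; j++) {
        if (!used[j] && (best == 0 || sc[j] > sc[best])) best = j
      }
      used[best] = 1
      print recs[best]
      print "$$$$"
    }
  }
' "$1" > "$2"
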