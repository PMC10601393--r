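# Five-lineage, eight-scenario design for the South Caucasus sweet-chestnut
# study system: Lesser Caucasus (I), West Greater Caucasus (II), Central
# Greater Caucasus (III), East Greater Caucasus (IV) and Europe (V).
# Times are generations before present; Ne are diploid effective sizes.

[settings]
n_loci = 9
generation_time = 100
locus_shape = 2

[lineages]
I   Ne=NeI   n=62
II  Ne=NeII  n=72
III Ne=NeIII n=65
IV  Ne=NeIV  n=40
V   Ne=NeV   n=27

# Scenario 1: deepest split separates I, IV and Europe (V); II diverges
# from I at t1; III arises by admixture between II and IV at ta.
[scenario 1]
admix time=ta target=III source1=II source2=IV ra=ra
split time=t1 derived=II ancestor=I
split time=t2 derived=IV,V ancestor=I
constraint ta < t1 < t2

# Scenario 2: as Scenario 1 but II never diverged from I before the
# admixture; II, IV and V all split from I at t2.
[scenario 2]
admix time=ta target=III source1=II source2=IV ra=ra
split time=t2 derived=II,IV,V ancestor=I
constraint ta < t2

# Scenario 3: a single simultaneous radiation of all lineages at t1.
[scenario 3]
split time=t1 derived=II,III,IV,V ancestor=I

# Scenario 4: west-east differentiation; II from I and IV from III
# recently, the two stems plus Europe joining at t2.
[scenario 4]
split time=t1 derived=II ancestor=I
split time=ta derived=IV ancestor=III
split time=t2 derived=III,V ancestor=I
constraint ta < t2
constraint t1 < t2

# Scenario 5: ladder through the west: III from II, then II and IV from I,
# Europe deepest.
[scenario 5]
split time=ta derived=III ancestor=II
split time=t1 derived=II,IV ancestor=I
split time=t2 derived=V ancestor=I
constraint ta < t1 < t2

# Scenario 6: III from IV in the east, then II and IV from I, Europe deepest.
[scenario 6]
split time=ta derived=III ancestor=IV
split time=t1 derived=II,IV ancestor=I
split time=t2 derived=V ancestor=I
constraint ta < t1 < t2

# Scenario 7: II from III, then III and IV from I, Europe deepest.
[scenario 7]
split time=ta derived=II ancestor=III
split time=t1 derived=III,IV ancestor=I
split time=t2 derived=V ancestor=I
constraint ta < t1 < t2

# Scenario 8: Lineage IV ancestral to all Caucasian lineages; Europe splits
# from IV deepest of all.
[scenario 8]
split time=ta derived=III ancestor=IV
split time=t1 derived=I,II ancestor=IV
split time=t2 derived=V ancestor=IV
constraint ta < t1 < t2

[priors]
NeI     = uniform(100, 30000)
NeII    = uniform(100, 30000)
NeIII   = uniform(100, 30000)
NeIV    = uniform(100, 30000)
NeV     = uniform(100, 30000)
t1      = uniform(10, 10000)
t2      = uniform(10, 10000)
ta      = uniform(10, 10000)
ra      = uniform(0.001, 0.999)
mu_mean = uniform(1e-5, 1e-3)
P_mean  = uniform(0.1, 0.3)
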