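# The fixed-step EAD protocols integrate ~1e8 steps per simulation; opt in
# to higher optimisation for the ODE core.
MCB_OPTFLAGS = -g -O3 -march=native -funroll-loops -fstack-protector-strong \
  -fvisibility-inlines-hidden -fmessage-length=0 -ftree-vectorize -pipe
override CXXFLAGS = $(MCB_OPTFLAGS)
override CXX17FLAGS = $(MCB_OPTFLAGS)
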