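phone	place	manner	frontness	closeness
p	bilabial	stop		
b	bilabial	stop		
t	alveolar	stop		
d	alveolar	stop		
k	velar	stop		
g	velar	stop		
f	labiodental	fricative		
v	labiodental	fricative		
th	dental	fricative		
dh	dental	fricative		
s	alveolar	fricative		
z	alveolar	fricative		
sh	postalveolar	fricative		
zh	postalveolar	fricative		
ch	postalveolar	affricate		
jh	postalveolar	affricate		
m				
n				
ng				
l				
r				
w				
y				
iy			front	close
ih			front	close
eh			front	mid
ae			front	open
aa			back	open
ao			back	mid
uw			back	close
uh			back	close
ah			central	mid
er			central	mid
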